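test_that("cohort simulation is reproducible and exact at its boundaries", {
  spec <- cohort_spec(5e4, 100, 0, exposure = 0.6, efficacy_i = 1,
                      efficacy_j = 0.8, seed = 101)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)  # fixed seed: bit-reproducible
  # no exposure: nobody is selected, differential exactly zero
  none <- simulate_cohort(cohort_spec(1e4, 100, exposure = 0, seed = 2))
  expect_identical(none$differential_i, 0)
  expect_identical(none$degree_of_control, 0)
  # zero efficacy: survival 1, truncation threshold -Inf, differential zero
  dud <- simulate_cohort(cohort_spec(1e4, 100, exposure = 0.7,
                                     efficacy_i = 0, seed = 3))
  expect_identical(dud$differential_i, 0)
  expect_equal(dud$exposed_survival_i, 1)
})

test_that("the empirical differential converges to the analytic value as 1/sqrt(N)", {
  st <- population_state(0, sigma = 20)
  analytic <- mono_selection_differential(st, "i", 1, 0.7)$differential
  sizes <- c(1e3, 1e4, 1e5)
  runs <- lapply(sizes, function(n) {
    simulate_cohort(cohort_spec(n, 0, exposure = 0.7, efficacy_i = 1,
                                seed = 515))
  })
  errs <- vapply(runs, function(r) abs(r$differential_i - analytic), numeric(1))
  ses <- vapply(runs, function(r) r$differential_i_se, numeric(1))
  # each run is consistent with the analytic value
  expect_true(all(errs < 3 * ses))
  # the standard error shrinks roughly as 1/sqrt(N) over two decades
  expect_lt(ses[3], ses[1] / 5)
})

test_that("empirical control converges to exposure * (1 - joint survival)", {
  spec <- cohort_spec(2e5, 100, 225, exposure = 0.6,
                      efficacy_i = 1, efficacy_j = 0.9, seed = 77)
  emp <- simulate_cohort(spec)
  expected <- 0.6 * (1 - emp$exposed_survival_i * emp$exposed_survival_j)
  expect_lt(abs(emp$degree_of_control - expected),
            3 * emp$degree_of_control_se)
})

test_that("empirical and theoretical truncation thresholds agree", {
  # the empirical-quantile mode recovers the same differential within noise
  th <- simulate_cohort(cohort_spec(2e5, 50, exposure = 0.8, efficacy_i = 0.9,
                                    seed = 31, threshold_mode = "theoretical"))
  em <- simulate_cohort(cohort_spec(2e5, 50, exposure = 0.8, efficacy_i = 0.9,
                                    seed = 31, threshold_mode = "empirical"))
  expect_lt(abs(th$differential_i - em$differential_i),
            3 * sqrt(th$differential_i_se^2 + em$differential_i_se^2))
})

test_that("cohort export writes one row per individual", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_cohort(cohort_spec(500, 100, 0, exposure = 0.5, efficacy_i = 1,
                            efficacy_j = 1, seed = 5), path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(df), 500)
  expect_named(df, c("prs_i", "prs_j", "exposed", "survives"))
})
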