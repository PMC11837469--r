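test_that("selection intensity matches the truncated-normal tail mean", {
  # closed form vs independent quadrature oracle
  p <- c(0.01, 0.05, 0.15, 0.3, 0.5, 0.8, 0.99)
  expect_equal(selection_intensity(p), intensity_by_integration(p),
               tolerance = 1e-9)
  expect_equal(selection_intensity(1), 0)
  expect_equal(selection_intensity(0.5), 0.7978846, tolerance = 1e-6)
  expect_equal(selection_intensity(0.05), 2.062713, tolerance = 1e-6)
  expect_error(selection_intensity(0), "positive")
  expect_error(selection_intensity(1.01), "not exceed 1")
  # values below the floor are clamped, not rejected
  expect_true(is.finite(selection_intensity(1e-30)))
})

test_that("monotherapy differential behaves at its boundary cases", {
  st <- population_state(0, sigma = 20)
  expect_equal(mono_selection_differential(st, "i", 1, 0)$differential, 0)
  expect_equal(mono_selection_differential(st, "i", 0, 0.7)$differential, 0)
  # full exposure over a fully lethal dose wipes out the population
  expect_error(mono_selection_differential(st, "i", 1.2, 1),
               "degenerate extinction")
  # full exposure, efficacy 1: survivors are the top 15%, S = 20 * i(0.15)
  res <- mono_selection_differential(st, "i", 1, 1)
  expect_equal(res$exposed_survival, 0.15)
  expect_equal(res$differential, 20 * selection_intensity(0.15))
})

test_that("mixture differentials reduce, symmetrise and ignore the partner at full exposure", {
  st <- population_state(100, 100, sigma = 20)
  params <- model_params()
  # ineffective partner: trait-i differential equals the monotherapy value
  mx <- mixture_selection_differentials(st, 0.9, 0, 0.6, params)
  mono <- mono_selection_differential(st, "i", 0.9, 0.6, params)
  expect_equal(mx$differential_i, mono$differential)
  # symmetric inputs give symmetric differentials
  sym <- mixture_selection_differentials(st, 0.8, 0.8, 0.5, params)
  expect_equal(sym$differential_i, sym$differential_j)
  # at exposure 1 there is no unexposed dilution: S_i = sigma * i(p_i),
  # independent of the partner's efficacy
  full_a <- mixture_selection_differentials(st, 1, 0.3, 1, params)
  full_b <- mixture_selection_differentials(st, 1, 0.9, 1, params)
  expect_equal(full_a$differential_i, full_b$differential_i)
  expect_equal(full_a$differential_i,
               20 * selection_intensity(full_a$exposed_survival_i))
})

test_that("a more effective partner dilutes selection (mixture dilution property)", {
  st <- population_state(100, 0, sigma = 20)
  eff_j <- seq(0, 1.2, by = 0.1)
  for (x in c(0.3, 0.6, 0.9)) {
    s_i <- mixture_selection_differentials(st, 1, eff_j, x)$differential_i
    expect_true(all(diff(s_i) <= 1e-12))  # partner efficacy up -> S_i down
    expect_true(s_i[1] > s_i[length(s_i)])
  }
})

test_that("the Breeder's equation response is plain arithmetic", {
  expect_equal(breeders_response(10, 10, 0.2, 1), 2)
  expect_equal(breeders_response(10, 10, 0, 1), 0)
  expect_equal(breeders_response(10, 10, 0.2, 2), 4)
  expect_equal(breeders_response(4, 8, 0.5, 1), 3)
})

test_that("cross-resistance adds the Falconer correlated response", {
  p0 <- model_params(cross_resistance = 0)
  r0 <- apply_cross_resistance(1.5, 0.7, 10, 5, p0)
  expect_equal(r0$total_response_i, 1.5)
  expect_equal(r0$total_response_j, 0.7)
  # alpha = 0.3, h2 = 0.2 both, partner differential 10: correlated term 0.6
  p1 <- model_params(cross_resistance = 0.3)
  r1 <- apply_cross_resistance(0, 0, 0, 10, p1)
  expect_equal(r1$total_response_i, 0.6)
  # negative correlation with positive partner selection drags trait i down
  pn <- model_params(cross_resistance = -0.3)
  rn <- apply_cross_resistance(0, 1, 5, 10, pn)
  expect_lt(rn$total_response_i, 0)
})

test_that("degree of control is exposure times kill fraction", {
  expect_equal(degree_of_control(1, 0), 1)
  expect_equal(degree_of_control(0.7, 0.5), 0.35)
  expect_equal(degree_of_control(0.4, 1), 0)
})

test_that("a single generation step composes the engine correctly", {
  params <- model_params()
  st <- population_state(50, 50)
  # no exposure, no costs: state unchanged
  ex0 <- exposure_config(female_exposure = 0)
  out0 <- single_generation_step(st, mixture(1, 1), ex0, params)
  expect_equal(out0$state$mean_prs_i, 50)
  expect_equal(out0$state$mean_prs_j, 50)
  # equal male and female exposure: equal sex-specific differentials
  ex1 <- exposure_config(female_exposure = 0.7, male_ratio = 1)
  out1 <- single_generation_step(st, monotherapy("i", 1), ex1, params)
  expect_equal(out1$outcome$differential_female_i,
               out1$outcome$differential_male_i)
  expect_gt(out1$state$mean_prs_i, 50)
  expect_equal(out1$state$mean_prs_j, 50)  # alpha = 0: no correlated change
  # unequal male exposure gives a smaller male differential
  ex2 <- exposure_config(female_exposure = 0.7, male_ratio = 0.5)
  out2 <- single_generation_step(st, monotherapy("i", 1), ex2, params)
  expect_lt(out2$outcome$differential_male_i,
            out2$outcome$differential_female_i)
  # degree of control uses female exposure and joint survival
  mx <- single_generation_step(st, mixture(1, 1), ex1, params)
  expect_equal(mx$outcome$degree_of_control,
               0.7 * (1 - mx$outcome$exposed_survival_i *
                        mx$outcome$exposed_survival_j))
  # fitness costs act even without a deployment
  pc <- model_params(cost_female_i = 2, cost_male_i = 2)
  outc <- single_generation_step(st, NULL, ex1, pc)
  expect_equal(outc$state$mean_prs_i, 50 - 0.2 * 2)
})

test_that("step response agrees with differential arithmetic and the cohort", {
  # one step from z = 0, h2 = 0.2, x = 0.7, efficacy 1: response follows
  # Eq.-style arithmetic from the analytic differential, which itself
  # matches the Monte-Carlo cohort
  params <- model_params()
  st <- population_state(0, sigma = 20)
  ex <- exposure_config(female_exposure = 0.7, male_ratio = 1)
  out <- single_generation_step(st, monotherapy("i", 1), ex, params)
  s_analytic <- mono_selection_differential(st, "i", 1, 0.7, params)$differential
  expect_equal(out$state$mean_prs_i, 0.2 * s_analytic)
  emp <- simulate_cohort(cohort_spec(2e5, 0, exposure = 0.7, efficacy_i = 1,
                                     seed = 424242))
  expect_lt(abs(s_analytic - emp$differential_i), 3 * emp$differential_i_se)
})

test_that("responses are non-negative with zero costs and non-negative alpha", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      st <- population_state(runif(1, 0, 2000), runif(1, 0, 2000))
      params <- model_params(cross_resistance = runif(1, 0, 1))
      ex <- exposure_config(female_exposure = runif(1, 0.05, 0.95))
      out <- single_generation_step(st, mixture(runif(1, 0, 1.2),
                                                runif(1, 0, 1.2)),
                                    ex, params)
      expect_gte(out$outcome$response_i, 0)
      expect_gte(out$outcome$response_j, 0)
    }
  })
})

test_that("selection over efficacy peaks at an interior dose when some escape exposure", {
  # moderate resistance, partial exposure: the change in bioassay survival
  # over the 0-1.2 efficacy grid has a hump; at full exposure it is
  # non-decreasing throughout
  params <- model_params()
  eff <- seq(0, 1.2, by = 0.1)
  st <- population_state(bioassay_to_prs(0.2), sigma = 20)
  delta_at <- function(x) {
    vapply(eff, function(e) {
      s <- mono_selection_differential(st, "i", e, x, params)$differential
      100 * (prs_to_bioassay(st$mean_prs_i + 0.2 * s) -
               prs_to_bioassay(st$mean_prs_i))
    }, numeric(1))
  }
  d_partial <- delta_at(0.5)
  peak <- which.max(d_partial)
  expect_gt(peak, 1)
  expect_lt(peak, length(eff))
  d_full <- delta_at(1)
  expect_true(all(diff(d_full) >= -1e-12))
})
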