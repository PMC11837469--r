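test_that("seeding uses the conventional rounded scores for standard levels", {
  expect_equal(seed_population(c(0, 5, 10, 20, 50, 80)),
               c(0, 47, 100, 225, 900, 3600))
  # non-standard levels invert exactly
  expect_equal(seed_population(30), bioassay_to_prs(0.3))
  # non-default scales always invert exactly
  sc <- resistance_scale(half_saturation = 500)
  expect_equal(seed_population(50, sc), 500)
  expect_error(seed_population(100), "\\[0, 100\\)")
})

test_that("the monotherapy grid has the right cardinality, order and edge cells", {
  grid <- run_mono_grid()
  expect_equal(nrow(grid), 13 * 10 * 6)
  # lexicographic sweep order: efficacy slowest, resistance fastest
  expect_equal(grid$efficacy, rep(seq(0, 12) / 10, each = 60))
  expect_equal(grid$resistance_i[1:6], c(0, 5, 10, 20, 50, 80))
  # efficacy 0: no selection, no control
  zero <- grid[grid$efficacy == 0, ]
  expect_true(all(zero$delta_bioassay_i == 0))
  expect_true(all(zero$degree_of_control == 0))
  # degenerate extinction cells: full exposure, above-LD100 dose on
  # susceptibles -> control 1, change undefined
  degen <- grid[grid$exposure == 1 & grid$exposed_survival_i == 0, ]
  expect_gt(nrow(degen), 0)
  expect_true(all(is.na(degen$delta_bioassay_i)))
  expect_true(all(degen$degree_of_control == 1))
  # everything else is finite with control in [0, 1]
  ok <- grid[!(grid$exposure == 1 & grid$exposed_survival_i == 0), ]
  expect_true(all(is.finite(ok$delta_bioassay_i)))
  expect_true(all(grid$degree_of_control >= 0 & grid$degree_of_control <= 1))
})

test_that("grid cells agree with the single-generation engine", {
  grid <- run_mono_grid()
  cell <- grid[grid$efficacy == 1 & grid$exposure == 0.7 &
                 grid$resistance_i == 10, ]
  st <- population_state(100, sigma = 20)
  ex <- exposure_config(female_exposure = 0.7, male_ratio = 1)
  out <- single_generation_step(st, monotherapy("i", 1), ex, model_params())
  expect_equal(cell$delta_bioassay_i,
               100 * (prs_to_bioassay(out$state$mean_prs_i) -
                        prs_to_bioassay(100)))
  expect_equal(cell$degree_of_control, out$outcome$degree_of_control)
})

test_that("the mixture grid is complete and symmetric under label swap", {
  grid <- run_mixture_grid()
  expect_equal(nrow(grid), 13 * 13 * 10 * 6 * 6)
  # swapping insecticide labels swaps the per-insecticide outcomes
  swapped <- grid[order(grid$efficacy_j, grid$efficacy_i, grid$exposure,
                        grid$resistance_j, grid$resistance_i), ]
  expect_equal(swapped$delta_bioassay_j, grid$delta_bioassay_i)
  expect_equal(swapped$delta_total, grid$delta_total)
  expect_equal(swapped$degree_of_control, grid$degree_of_control)
  # equal efficacy and resistance: equal per-insecticide change
  diag <- grid[grid$efficacy_i == grid$efficacy_j &
                 grid$resistance_i == grid$resistance_j, ]
  expect_equal(diag$delta_bioassay_i, diag$delta_bioassay_j)
})

test_that("partner efficacy dampens selection at partial exposure", {
  grid <- run_mixture_grid()
  # for each (efficacy_i, resistance pair) slice at exposure 0.6, delta_i is
  # non-increasing as the partner's efficacy rises (mutual protection)
  sl <- grid[grid$exposure == 0.6 & grid$resistance_i == 10 &
               grid$resistance_j == 10, ]
  for (ei in unique(sl$efficacy_i)) {
    d <- sl$delta_bioassay_i[sl$efficacy_i == ei][order(sl$efficacy_j[sl$efficacy_i == ei])]
    expect_true(all(diff(d) <= 1e-12))
  }
  # at full exposure the total change is non-decreasing along the equal-
  # efficacy diagonal (no unexposed dilution)
  dg <- grid[grid$exposure == 1 & grid$efficacy_i == grid$efficacy_j &
               grid$resistance_i == 20 & grid$resistance_j == 20, ]
  dg <- dg[order(dg$efficacy_i), ]
  expect_true(all(diff(dg$delta_total) >= -1e-12))
})
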