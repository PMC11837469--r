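test_that("dispersal mixes toward the pooled mean and conserves the global mean", {
  # worked example: coverage 0.7, dispersal 0.2, site 100 vs refugia 0
  d <- disperse(100, 0, coverage = 0.7, dispersal = 0.2)
  expect_equal(d$site, 94)
  expect_equal(d$refugia, 14)
  expect_equal(0.7 * d$site + 0.3 * d$refugia, 70)
  # no dispersal, or identical demes: nothing moves
  same <- disperse(c(10, 20), c(10, 20), 0.7, 0.9)
  expect_equal(same$site, c(10, 20))
  none <- disperse(c(10, 20), c(3, 4), 0.7, 0)
  expect_equal(none$site, c(10, 20))
  expect_equal(none$refugia, c(3, 4))
})

test_that("dispersal conserves the coverage-weighted mean across 500 perturbed rounds", {
  withr::with_seed(11, {
    site <- c(0, 0); ref <- c(0, 0)
    cov <- 0.7; th <- 0.2
    for (g in 1:500) {
      site <- site + runif(2, 0, 5)           # stand-in for selection
      global <- cov * site + (1 - cov) * ref
      mixed <- disperse(site, ref, cov, th)
      site <- mixed$site; ref <- mixed$refugia
      expect_equal(cov * site + (1 - cov) * ref, global, tolerance = 1e-12)
    }
  })
})

test_that("degenerate configurations terminate as expected", {
  # both insecticides already past the withdrawal threshold: lifespan 0
  hot <- strategy_config(initial_means = c(300, 300),
                         record_trajectory = FALSE)
  for (arm in c("sequence", "mixture")) {
    hot$strategy <- arm
    out <- run_strategy(hot)
    expect_equal(out$lifespan_generations, 0L)
    expect_false(out$censored)
  }
  # zero heritability: no evolution, censored at the 500-generation cap
  frozen <- strategy_config(params = model_params(h2_i = 0, h2_j = 0),
                            record_trajectory = FALSE)
  out <- run_strategy(frozen)
  expect_true(out$censored)
  expect_equal(out$lifespan_generations, 500L)
  expect_equal(out$lifespan_years, 50)
})

test_that("the mixture arm without decay reduces to chained generation steps", {
  cfg <- strategy_config(strategy = "mixture",
                         decay_i = decay_profile(mode = "none"),
                         decay_j = decay_profile(mode = "none"),
                         max_generations = 30)
  out <- run_strategy(cfg)
  # manual chain: selection in the site, nothing in refugia, then dispersal
  site <- population_state(0, 0, 20)
  ref_z <- c(0, 0)
  ex <- exposure_config()
  for (g in 1:30) {
    stepped <- single_generation_step(site, mixture(1, 1), ex, model_params())
    mixed <- disperse(c(stepped$state$mean_prs_i, stepped$state$mean_prs_j),
                      ref_z, 0.7, 0.2)
    site <- population_state(mixed$site[1], mixed$site[2], 20)
    ref_z <- mixed$refugia
  }
  expect_equal(tail(out$trajectory$site_prs_i, 1), site$mean_prs_i,
               tolerance = 1e-12)
  expect_equal(tail(out$trajectory$refugia_prs_j, 1), ref_z[2],
               tolerance = 1e-12)
  # resistance to a deployed insecticide never falls while it is deployed
  expect_true(all(diff(out$trajectory$site_prs_i) >= -1e-12))
})

test_that("the sequence arm withdraws, replaces and terminates on thresholds", {
  cfg <- strategy_config(decay_i = decay_profile(mode = "none"),
                         decay_j = decay_profile(mode = "none"))
  out <- run_strategy(cfg)
  ev <- out$events
  # insecticide i is deployed first, withdrawn at the 10% threshold, then j
  deploys <- ev[ev$event == "deploy", ]
  expect_equal(deploys$insecticide[1:2], c("i", "j"))
  wd_gen <- ev$generation[ev$event == "withdraw" & ev$insecticide == "i"][1]
  expect_equal(deploys$generation[2], wd_gen + 1)  # replacement next generation
  # at withdrawal the monitored survival had reached the threshold
  expect_gte(out$trajectory$bioassay_i[wd_gen], 10)
  expect_lt(out$trajectory$bioassay_i[wd_gen - 1], 10)
  # the run ended because nothing was left to deploy
  expect_false(out$censored)
  expect_match(out$termination_reason, "no insecticide available")
})

test_that("scheduled redeployment resets the decay clock", {
  cfg <- strategy_config(strategy = "mixture", max_generations = 65)
  out <- run_strategy(cfg)
  tr <- out$trajectory
  # during generations 31 and 61 the efficacy snaps back to deployed level
  expect_equal(tr$efficacy_i[31], 1)
  expect_equal(tr$efficacy_i[61], 1)
  expect_lt(tr$efficacy_i[30], tr$efficacy_i[31])
  refreshes <- out$events[out$events$event == "refresh", ]
  expect_equal(refreshes$generation[1:2], c(31, 61))
})

test_that("scenario sweeps produce the full comparison factorial", {
  quick <- list(max_generations = 40)
  s1 <- run_scenario(1, overrides = quick)
  expect_equal(nrow(s1), 81 + 9)
  expect_equal(sum(s1$decay_mode == "none"), 9)
  expect_setequal(unique(s1$cross_resistance), c(-0.3, 0, 0.3))
  expect_setequal(unique(s1$mixture_omega0), c(1, 0.75, 0.5))
  expect_equal(s1$difference_years,
               s1$lifespan_mixture_years - s1$lifespan_sequence_years)
  expect_error(run_scenario(4), "unknown scenario")
  # scenario 2 seeds insecticide i at 2.7% initial bioassay survival
  expect_equal(round(100 * prs_to_bioassay(25), 1), 2.7)
})
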