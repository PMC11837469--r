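# Independent numeric-integration oracle for the truncated-normal tail mean:
# mean of the upper-p tail of a standard normal, computed by quadrature
# rather than the closed form used by selection_intensity().
intensity_by_integration <- function(p) {
  vapply(p, function(pp) {
    if (pp == 1) return(0)
    stats::integrate(function(x) x * stats::dnorm(x),
                     stats::qnorm(1 - pp), Inf,
                     rel.tol = 1e-12)$value / pp
  }, numeric(1))
}

# Random parameter settings for analytic-vs-cohort comparisons.
draw_oracle_settings <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      resistance_i = runif(n, 0, 0.8),
      resistance_j = runif(n, 0, 0.8),
      efficacy_i = runif(n, 0.2, 1.2),
      efficacy_j = runif(n, 0.2, 1.2),
      exposure = runif(n, 0.1, 1),
      mix = rep(c(FALSE, TRUE), length.out = n),
      seed = sample.int(1e6, n)
    )
  })
}

# Compare analytic differentials with the Monte-Carlo cohort for one
# setting; returns the vector of |analytic - empirical| / se ratios.
oracle_z_scores <- function(setting, n_individuals) {
  sc <- resistance_scale()
  z_i <- bioassay_to_prs(setting$resistance_i, sc)
  z_j <- bioassay_to_prs(setting$resistance_j, sc)
  params <- model_params()
  if (setting$mix) {
    state <- population_state(z_i, z_j)
    an <- mixture_selection_differentials(state, setting$efficacy_i,
                                          setting$efficacy_j,
                                          setting$exposure, params)
    emp <- simulate_cohort(cohort_spec(
      n_individuals, z_i, z_j, exposure = setting$exposure,
      efficacy_i = setting$efficacy_i, efficacy_j = setting$efficacy_j,
      seed = setting$seed))
    c(abs(an$differential_i - emp$differential_i) / emp$differential_i_se,
      abs(an$differential_j - emp$differential_j) / emp$differential_j_se)
  } else {
    state <- population_state(z_i)
    an <- mono_selection_differential(state, "i", setting$efficacy_i,
                                      setting$exposure, params)
    emp <- simulate_cohort(cohort_spec(
      n_individuals, z_i, exposure = setting$exposure,
      efficacy_i = setting$efficacy_i, seed = setting$seed))
    abs(an$differential - emp$differential_i) / emp$differential_i_se
  }
}
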