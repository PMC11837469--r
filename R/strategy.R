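#' Dispersal between the treated site and untreated refugia
#'
#' Each generation a proportion `dispersal` of each deme mixes into a common
#' pool whose mean is the coverage-weighted average of the two demes; each
#' deme's new mean is the dispersal-weighted blend of its own mean and the
#' pool. The coverage-weighted global mean of every trait is conserved
#' exactly.
#'
#' @param site_means Mean PRS value(s) in the treated site (one per trait).
#' @param refugia_means Mean PRS value(s) in the refugia, same length.
#' @param coverage Proportion C of the population in the treated site.
#' @param dispersal Dispersal proportion theta.
#' @return A list with updated `site` and `refugia` mean vectors.
#' @examples
#' disperse(100, 0, coverage = 0.7, dispersal = 0.2)  # site 94, refugia 14
#' @export
disperse <- function(site_means, refugia_means, coverage, dispersal) {
  stopifnot(is.numeric(site_means), is.numeric(refugia_means),
            length(site_means) == length(refugia_means),
            coverage >= 0, coverage <= 1, dispersal >= 0, dispersal <= 1)
  pooled <- coverage * site_means + (1 - coverage) * refugia_means
  list(
    site = (1 - dispersal) * site_means + dispersal * pooled,
    refugia = (1 - dispersal) * refugia_means + dispersal * pooled
  )
}

#' Configuration of a multi-generation deployment strategy run
#'
#' Describes a two-deme (treated site plus untreated refugia) simulation of
#' one resistance-management strategy: either a sequence of monotherapies
#' (each insecticide deployed until its bioassay survival in the treated
#' deme reaches the withdrawal threshold, then replaced by the next
#' available one) or a two-insecticide mixture (terminated when either
#' component reaches the withdrawal threshold). Deployed insecticide decays
#' per its [decay_profile()] and is refreshed (redeployed at full efficacy)
#' every `deployment_frequency` generations, the standard interval between
#' net distribution rounds.
#'
#' @param strategy `"sequence"` or `"mixture"`.
#' @param decay_i,decay_j [decay_profile()]s of the two insecticides; their
#'   `deployed_efficacy` is the dose used by the sequence arm.
#' @param params A [model_params()].
#' @param exposure An [exposure_config()] (female exposure, male ratio,
#'   coverage, dispersal).
#' @param initial_means Length-2 vector of initial mean PRS (both demes).
#' @param sigma Phenotypic standard deviation of the PRS.
#' @param withdrawal_threshold Bioassay-survival percentage at which a
#'   deployed insecticide is withdrawn (default 10).
#' @param return_threshold Bioassay-survival percentage below which a
#'   withdrawn insecticide becomes available again (default 8; must be
#'   below the withdrawal threshold).
#' @param deployment_frequency Generations between scheduled redeployments
#'   (default 30, ~3 years at 10 generations per year).
#' @param max_generations Simulation cap (default 500, i.e. 50 years).
#' @param generations_per_year Used to express lifespans in years
#'   (default 10).
#' @param mixture_deployed_efficacy Optional deployed efficacy for both
#'   mixture components (e.g. 0.75 or 0.5 for reduced-dose mixtures),
#'   overriding the profiles' `deployed_efficacy` in the mixture arm only.
#' @param monitor `"site"` (default: thresholds are evaluated on the
#'   treated-deme mean, where deployment decisions are made) or `"global"`
#'   (coverage-weighted mean of both demes).
#' @param record_trajectory Keep the per-generation trajectory (default
#'   `TRUE`).
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("sequence", "mixture"),
                            decay_i = decay_profile(),
                            decay_j = decay_profile(),
                            params = model_params(),
                            exposure = exposure_config(),
                            initial_means = c(0, 0),
                            sigma = 20,
                            withdrawal_threshold = 10,
                            return_threshold = 8,
                            deployment_frequency = 30,
                            max_generations = 500,
                            generations_per_year = 10,
                            mixture_deployed_efficacy = NULL,
                            monitor = c("site", "global"),
                            record_trajectory = TRUE) {
  strategy <- match.arg(strategy)
  monitor <- match.arg(monitor)
  stopifnot(
    inherits(decay_i, "decay_profile"), inherits(decay_j, "decay_profile"),
    inherits(params, "model_params"), inherits(exposure, "exposure_config"),
    "initial_means must be two finite numbers" =
      is.numeric(initial_means) && length(initial_means) == 2 &&
      all(is.finite(initial_means)),
    "sigma must be positive" = is.numeric(sigma) && sigma > 0,
    "thresholds are bioassay-survival percentages in (0, 100)" =
      withdrawal_threshold > 0 && withdrawal_threshold < 100 &&
      return_threshold > 0 && return_threshold < 100,
    "return_threshold must be below withdrawal_threshold" =
      return_threshold < withdrawal_threshold,
    "deployment_frequency must be at least 1" = deployment_frequency >= 1,
    "max_generations must be at least 1" = max_generations >= 1,
    "generations_per_year must be positive" = generations_per_year > 0
  )
  if (!is.null(mixture_deployed_efficacy)) {
    stopifnot("mixture_deployed_efficacy must be a single non-negative number" =
                is.numeric(mixture_deployed_efficacy) &&
                length(mixture_deployed_efficacy) == 1 &&
                mixture_deployed_efficacy >= 0)
  }
  structure(
    list(strategy = strategy, decay_i = decay_i, decay_j = decay_j,
         params = params, exposure = exposure,
         initial_means = initial_means, sigma = sigma,
         withdrawal_threshold = withdrawal_threshold,
         return_threshold = return_threshold,
         deployment_frequency = deployment_frequency,
         max_generations = max_generations,
         generations_per_year = generations_per_year,
         mixture_deployed_efficacy = mixture_deployed_efficacy,
         monitor = monitor, record_trajectory = record_trajectory),
    class = "strategy_config"
  )
}

# Lean per-generation update of one deme, shared by both arms.
# kind: "none" (refugia / nothing deployed), "mono" (trait 1 or 2), "mix".
.lean_step <- function(z, sigma, kind, trait_idx, eff_i, eff_j, x_f, x_m, par) {
  s_f <- c(0, 0); s_m <- c(0, 0); surv <- c(1, 1); joint <- 1
  if (kind == "mono") {
    eff <- if (trait_idx == 1L) eff_i else eff_j
    p <- field_survival(prs_to_bioassay(z[trait_idx], par$scale), eff,
                        par$field_params)
    s_f[trait_idx] <- .differential_kernel(p, p, x_f, sigma, par$survival_floor)
    s_m[trait_idx] <- .differential_kernel(p, p, x_m, sigma, par$survival_floor)
    surv[trait_idx] <- p
    joint <- p
  } else if (kind == "mix") {
    p1 <- field_survival(prs_to_bioassay(z[1], par$scale), eff_i,
                         par$field_params)
    p2 <- field_survival(prs_to_bioassay(z[2], par$scale), eff_j,
                         par$field_params)
    joint <- p1 * p2
    s_f <- c(.differential_kernel(p1, joint, x_f, sigma, par$survival_floor),
             .differential_kernel(p2, joint, x_f, sigma, par$survival_floor))
    s_m <- c(.differential_kernel(p1, joint, x_m, sigma, par$survival_floor),
             .differential_kernel(p2, joint, x_m, sigma, par$survival_floor))
    surv <- c(p1, p2)
  }
  d_f <- s_f - c(par$cost_female_i, par$cost_female_j)
  d_m <- s_m - c(par$cost_male_i, par$cost_male_j)
  md <- (d_f + d_m) / 2
  resp <- c(par$h2_i, par$h2_j) * md * par$exposure_scaling
  co <- par$cross_resistance * sqrt(par$h2_i * par$h2_j) * par$exposure_scaling
  list(z = z + resp + co * rev(md), surv = surv, joint = joint)
}

#' Run one multi-generation strategy simulation
#'
#' Per generation the order of events is: availability/deployment decisions
#' (withdrawn insecticides return when their monitored survival drops below
#' the return threshold; the sequence arm deploys the first available
#' insecticide when none is deployed), scheduled redeployment every
#' `deployment_frequency` generations (decay clock reset), efficacy lookup
#' from the decay profiles, insecticide selection in the treated deme,
#' fitness-cost-only selection in the refugia, dispersal, and threshold
#' monitoring. The run terminates when no insecticide is available (sequence)
#' or either mixture component reaches the withdrawal threshold (mixture),
#' or is censored at `max_generations`.
#'
#' @param config A [strategy_config()].
#' @return An object of class `strategy_outcome`: a list with
#'   `lifespan_generations`, `lifespan_years`, `censored`,
#'   `termination_reason`, an `events` tibble (deploy / withdraw / refresh /
#'   return / terminate, with generation stamps) and, when requested, a
#'   per-generation `trajectory` tibble.
#' @export
run_strategy <- function(config) {
  stopifnot(inherits(config, "strategy_config"))
  par <- config$params
  x_f <- config$exposure$female_exposure
  x_m <- config$exposure$male_ratio * x_f
  cov <- config$exposure$coverage
  th <- config$exposure$dispersal
  profiles <- list(config$decay_i, config$decay_j)
  if (config$strategy == "mixture" &&
      !is.null(config$mixture_deployed_efficacy)) {
    profiles <- lapply(profiles, function(p) {
      p$deployed_efficacy <- config$mixture_deployed_efficacy
      p
    })
  }
  site <- config$initial_means
  ref <- config$initial_means
  monitored <- function(site, ref) {
    z <- if (config$monitor == "site") site else cov * site + (1 - cov) * ref
    100 * prs_to_bioassay(z, par$scale)
  }

  max_gen <- config$max_generations
  record <- isTRUE(config$record_trajectory)
  if (record) {
    traj <- matrix(NA_real_, nrow = max_gen, ncol = 10,
                   dimnames = list(NULL, c(
                     "deployed", "tau", "efficacy_i", "efficacy_j",
                     "site_prs_i", "site_prs_j", "refugia_prs_i",
                     "refugia_prs_j", "bioassay_i", "bioassay_j")))
    controls <- numeric(max_gen)
  }
  events <- list()
  log_event <- function(gen, event, what) {
    events[[length(events) + 1L]] <<-
      list(generation = gen, event = event, insecticide = what)
  }

  deployed <- 0L       # 0 = none, 1 = insecticide i, 2 = j, 3 = mixture
  tau <- 0L
  withdrawn <- c(FALSE, FALSE)
  lifespan <- max_gen
  censored <- TRUE
  reason <- "reached maximum duration"

  if (config$strategy == "mixture") {
    surv0 <- monitored(site, ref)
    if (any(surv0 >= config$withdrawal_threshold)) {
      lifespan <- 0L
      return(.strategy_outcome(0L, FALSE,
                               "no insecticide available: initial resistance at or above the withdrawal threshold",
                               config, NULL, NULL))
    }
    deployed <- 3L
    log_event(1L, "deploy", "mixture")
  }

  for (gen in seq_len(max_gen)) {
    surv_now <- monitored(site, ref)
    # withdrawn insecticides return below the return threshold
    back <- withdrawn & (surv_now < config$return_threshold)
    if (any(back)) {
      withdrawn[back] <- FALSE
      for (k in which(back)) log_event(gen, "return", c("i", "j")[k])
    }
    if (config$strategy == "sequence" && deployed == 0L) {
      avail <- which(!withdrawn & surv_now < config$withdrawal_threshold)
      if (length(avail) == 0L) {
        lifespan <- gen - 1L
        censored <- FALSE
        reason <- "no insecticide available"
        log_event(gen, "terminate", "none")
        break
      }
      deployed <- avail[1L]
      tau <- 0L
      log_event(gen, "deploy", c("i", "j")[deployed])
    }
    if (deployed != 0L && tau >= config$deployment_frequency) {
      tau <- 0L
      log_event(gen, "refresh",
                if (deployed == 3L) "mixture" else c("i", "j")[deployed])
    }

    if (deployed == 3L) {
      eff_i <- efficacy_at(profiles[[1L]], tau)
      eff_j <- efficacy_at(profiles[[2L]], tau)
      st <- .lean_step(site, config$sigma, "mix", NA_integer_,
                       eff_i, eff_j, x_f, x_m, par)
    } else if (deployed != 0L) {
      eff <- efficacy_at(profiles[[deployed]], tau)
      eff_i <- if (deployed == 1L) eff else 0
      eff_j <- if (deployed == 2L) eff else 0
      st <- .lean_step(site, config$sigma, "mono", deployed,
                       eff_i, eff_j, x_f, x_m, par)
    } else {
      eff_i <- eff_j <- 0
      st <- .lean_step(site, config$sigma, "none", NA_integer_,
                       0, 0, x_f, x_m, par)
    }
    rf <- .lean_step(ref, config$sigma, "none", NA_integer_, 0, 0, 0, 0, par)
    mixed <- disperse(st$z, rf$z, cov, th)
    site <- mixed$site
    ref <- mixed$refugia
    if (deployed != 0L) tau <- tau + 1L

    surv_post <- monitored(site, ref)
    if (record) {
      traj[gen, ] <- c(deployed, tau, eff_i, eff_j, site, ref, surv_post)
      controls[gen] <- degree_of_control(x_f,
                                         if (deployed == 0L) 1 else st$joint)
    }

    if (config$strategy == "sequence" && deployed %in% c(1L, 2L) &&
        surv_post[deployed] >= config$withdrawal_threshold) {
      withdrawn[deployed] <- TRUE
      log_event(gen, "withdraw", c("i", "j")[deployed])
      deployed <- 0L
    } else if (config$strategy == "mixture" &&
               any(surv_post >= config$withdrawal_threshold)) {
      lifespan <- gen
      censored <- FALSE
      reason <- "mixture component reached the withdrawal threshold"
      log_event(gen, "terminate", "mixture")
      break
    }
  }

  trajectory <- NULL
  if (record) {
    kept <- seq_len(min(lifespan + 1L, max_gen))
    kept <- kept[!is.na(traj[kept, "tau"])]
    trajectory <- tibble::as_tibble(traj[kept, , drop = FALSE])
    trajectory$generation <- kept
    trajectory$degree_of_control <- controls[kept]
  }
  ev <- if (length(events)) dplyr::bind_rows(lapply(events, tibble::as_tibble))
        else tibble::tibble(generation = integer(), event = character(),
                            insecticide = character())
  .strategy_outcome(lifespan, censored, reason, config, trajectory, ev)
}

.strategy_outcome <- function(lifespan, censored, reason, config, trajectory,
                              events) {
  structure(
    list(lifespan_generations = as.integer(lifespan),
         lifespan_years = lifespan / config$generations_per_year,
         censored = censored,
         termination_reason = reason,
         strategy = config$strategy,
         trajectory = trajectory,
         events = events),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: %d generations (%.1f years)%s — %s\n",
              x$strategy, x$lifespan_generations, x$lifespan_years,
              if (x$censored) " [censored]" else "", x$termination_reason))
  invisible(x)
}

#' Compare the mixture strategy against the monotherapy sequence
#'
#' Runs both arms from identical initial conditions and insecticide
#' properties and returns the lifespan difference in years
#' (mixture minus sequence). Positive values favour the mixture. Censored
#' lifespans enter the difference at the cap.
#'
#' @param config A [strategy_config()]; its `strategy` field is ignored
#'   (both arms are run). `mixture_deployed_efficacy` applies to the mixture
#'   arm only, so a reduced-dose mixture can be compared against a full-dose
#'   sequence.
#' @return A list with `difference_years`, `sequence` and `mixture`
#'   ([run_strategy()] outcomes).
#' @export
compare_strategies <- function(config) {
  stopifnot(inherits(config, "strategy_config"))
  cfg_seq <- config; cfg_seq$strategy <- "sequence"
  cfg_mix <- config; cfg_mix$strategy <- "mixture"
  out_seq <- run_strategy(cfg_seq)
  out_mix <- run_strategy(cfg_mix)
  list(
    difference_years = out_mix$lifespan_years - out_seq$lifespan_years,
    sequence = out_seq,
    mixture = out_mix
  )
}

#' Run a full scenario sweep of strategy comparisons
#'
#' Reproduces the three evaluation scenarios: scenario 1 uses the default
#' parameters; scenario 2 starts with mismatched initial resistance (mean
#' PRS 25 for insecticide i, i.e. 2.7% bioassay survival, and 0 for j);
#' scenario 3 uses mismatched heritabilities (0.15 for trait i, 0.25 for
#' trait j). Each scenario sweeps the full factorial of base decay rates
#' \{0.005, 0.015, 0.025\} per insecticide, cross-resistance
#' \{-0.3, 0, 0.3\} and mixture deployed efficacy \{1, 0.75, 0.5\}
#' (81 comparisons under two-stage decay) plus a no-decay companion set over
#' cross-resistance and mixture dose (9 comparisons). The sequence arm
#' always deploys at full dose.
#'
#' @param scenario_id 1, 2 or 3.
#' @param overrides Named list of [strategy_config()] arguments to override
#'   (e.g. `list(max_generations = 100)`).
#' @return A tibble with one row per comparison: scenario, decay mode, base
#'   decay rates, cross-resistance, mixture deployed efficacy, both
#'   lifespans (generations and years), censoring flags and the lifespan
#'   difference in years (mixture minus sequence).
#' @export
run_scenario <- function(scenario_id, overrides = list()) {
  if (!scenario_id %in% 1:3) stop("unknown scenario id: ", scenario_id)
  base_rates <- c(0.005, 0.015, 0.025)
  alphas <- c(-0.3, 0, 0.3)
  mix_doses <- c(1, 0.75, 0.5)
  cells <- dplyr::bind_rows(
    tidyr::expand_grid(decay_mode = "two_stage",
                       base_rate_i = base_rates, base_rate_j = base_rates,
                       cross_resistance = alphas, mixture_omega0 = mix_doses),
    tidyr::expand_grid(decay_mode = "none",
                       base_rate_i = 0, base_rate_j = 0,
                       cross_resistance = alphas, mixture_omega0 = mix_doses)
  )

  h2 <- switch(scenario_id, `1` = c(0.2, 0.2), `2` = c(0.2, 0.2),
               `3` = c(0.15, 0.25))
  init <- switch(scenario_id, `1` = c(0, 0), `2` = c(25, 0), `3` = c(0, 0))

  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    args <- list(
      decay_i = decay_profile(deployed_efficacy = 1,
                              base_rate = cell$base_rate_i,
                              mode = cell$decay_mode),
      decay_j = decay_profile(deployed_efficacy = 1,
                              base_rate = cell$base_rate_j,
                              mode = cell$decay_mode),
      params = model_params(h2_i = h2[1], h2_j = h2[2],
                            cross_resistance = cell$cross_resistance),
      initial_means = init,
      mixture_deployed_efficacy = cell$mixture_omega0,
      record_trajectory = FALSE
    )
    args[names(overrides)] <- overrides
    cmp <- compare_strategies(do.call(strategy_config, args))
    rows[[r]] <- tibble::tibble(
      scenario = scenario_id,
      decay_mode = cell$decay_mode,
      base_rate_i = cell$base_rate_i, base_rate_j = cell$base_rate_j,
      cross_resistance = cell$cross_resistance,
      mixture_omega0 = cell$mixture_omega0,
      lifespan_sequence_generations = cmp$sequence$lifespan_generations,
      lifespan_mixture_generations = cmp$mixture$lifespan_generations,
      lifespan_sequence_years = cmp$sequence$lifespan_years,
      lifespan_mixture_years = cmp$mixture$lifespan_years,
      censored_sequence = cmp$sequence$censored,
      censored_mixture = cmp$mixture$censored,
      difference_years = cmp$difference_years
    )
  }
  dplyr::bind_rows(rows)
}
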