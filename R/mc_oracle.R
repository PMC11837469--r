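#' Specification of an individual-based Monte-Carlo cohort
#'
#' Describes a cohort with exactly the statistical structure the analytic
#' selection engine assumes: per-trait PRS values drawn from independent
#' normals with fixed standard deviation, Bernoulli insecticide exposure,
#' and deterministic top-fraction (truncation) survival of exposed
#' individuals, applied sequentially for mixtures. Simulating such cohorts
#' gives a brute-force empirical estimate of the selection differentials and
#' the degree of control, used to cross-check the closed-form expressions.
#'
#' @param n_individuals Cohort size (>= 1).
#' @param mean_prs_i,mean_prs_j Mean PRS per trait (`mean_prs_j = NULL` for
#'   a monotherapy cohort).
#' @param sigma Phenotypic standard deviation.
#' @param exposure Bernoulli exposure probability.
#' @param efficacy_i,efficacy_j Current insecticide efficacies
#'   (`efficacy_j = NULL` for monotherapy).
#' @param seed Integer seed; a fixed seed gives bit-reproducible output.
#' @param scale A [resistance_scale()].
#' @param field_params A [field_survival_params()].
#' @param threshold_mode `"theoretical"` (default): the truncation threshold
#'   is the exact normal quantile for the intended survival fraction, so the
#'   comparison probes the dilution/averaging algebra rather than quantile
#'   estimation; `"empirical"`: the cohort's own order statistic is used.
#' @param n_batches Number of batches for batch-mean standard errors.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, mean_prs_i, mean_prs_j = NULL,
                        sigma = 20, exposure = 0.7,
                        efficacy_i = 1, efficacy_j = NULL,
                        seed = 1L,
                        scale = resistance_scale(),
                        field_params = field_survival_params(),
                        threshold_mode = c("theoretical", "empirical"),
                        n_batches = 40L) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(
    "n_individuals must be a positive count" =
      is.numeric(n_individuals) && n_individuals >= 1,
    "exposure must lie in [0, 1]" = exposure >= 0 && exposure <= 1,
    "sigma must be positive" = sigma > 0,
    "efficacy_i must be non-negative" = efficacy_i >= 0,
    "seed must be a single number" = is.numeric(seed) && length(seed) == 1,
    "n_batches must be at least 2" = n_batches >= 2,
    inherits(scale, "resistance_scale"),
    inherits(field_params, "field_survival_params")
  )
  mix <- !is.null(efficacy_j)
  if (mix && is.null(mean_prs_j)) {
    stop("a mixture cohort needs mean_prs_j")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         mean_prs_i = mean_prs_i, mean_prs_j = mean_prs_j,
         sigma = sigma, exposure = exposure,
         efficacy_i = efficacy_i, efficacy_j = efficacy_j,
         seed = as.integer(seed), scale = scale, field_params = field_params,
         threshold_mode = threshold_mode, n_batches = as.integer(n_batches)),
    class = "cohort_spec"
  )
}

# batch-mean standard error of a per-batch statistic
.batch_se <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  stats::sd(values) / sqrt(length(values))
}

#' Simulate one cohort and measure selection empirically
#'
#' Draws the cohort, applies Bernoulli exposure and truncation survival, and
#' returns the empirical selection differentials (mean PRS of the parental
#' survivors minus the cohort mean, per trait), the empirical degree of
#' control (fraction of the cohort killed), and batch-mean standard errors
#' for each. Field survival per insecticide is computed from the specified
#' cohort mean, matching the analytic engine's mean-evaluation convention.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `differential_i` (+ `_se`), `differential_j`
#'   (+ `_se`, `NA` for monotherapy), `degree_of_control` (+ `_se`),
#'   `exposed_survival_i`, `exposed_survival_j`, `n_parents` and a
#'   `degenerate` flag (full exposure with zero survivors).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mix <- !is.null(spec$efficacy_j)
  p_i <- field_survival(prs_to_bioassay(spec$mean_prs_i, spec$scale),
                        spec$efficacy_i, spec$field_params)
  p_j <- if (mix) {
    field_survival(prs_to_bioassay(spec$mean_prs_j, spec$scale),
                   spec$efficacy_j, spec$field_params)
  } else {
    NA_real_
  }

  n <- spec$n_individuals
  res <- withr::with_seed(spec$seed, {
    z_i <- stats::rnorm(n, spec$mean_prs_i, spec$sigma)
    z_j <- if (mix) stats::rnorm(n, spec$mean_prs_j, spec$sigma) else NULL
    exposed <- stats::runif(n) < spec$exposure

    thr <- function(p, mean, values) {
      if (p >= 1) return(-Inf)
      if (p <= 0) return(Inf)
      if (spec$threshold_mode == "theoretical") {
        stats::qnorm(1 - p, mean = mean, sd = spec$sigma)
      } else {
        stats::quantile(values, 1 - p, names = FALSE)
      }
    }
    thr_i <- thr(p_i, spec$mean_prs_i, z_i)
    survives <- !exposed | (z_i > thr_i)
    if (mix) {
      thr_j <- thr(p_j, spec$mean_prs_j, z_j)
      survives <- survives & (!exposed | (z_j > thr_j))
    }
    list(z_i = z_i, z_j = z_j, survives = survives)
  })

  survives <- res$survives
  n_parents <- sum(survives)
  degenerate <- n_parents == 0L
  if (degenerate) {
    return(list(differential_i = NA_real_, differential_i_se = NA_real_,
                differential_j = NA_real_, differential_j_se = NA_real_,
                degree_of_control = 1, degree_of_control_se = 0,
                exposed_survival_i = p_i, exposed_survival_j = p_j,
                n_parents = 0L, degenerate = TRUE))
  }

  batch <- rep(seq_len(spec$n_batches), length.out = n)
  emp_diff <- function(z) {
    overall <- mean(z[survives]) - mean(z)
    per_batch <- vapply(seq_len(spec$n_batches), function(b) {
      sel <- batch == b
      sb <- survives & sel
      if (!any(sb)) return(NA_real_)
      mean(z[sb]) - mean(z[sel])
    }, numeric(1))
    c(overall, .batch_se(per_batch))
  }
  d_i <- emp_diff(res$z_i)
  d_j <- if (mix) emp_diff(res$z_j) else c(NA_real_, NA_real_)
  ctrl_batch <- vapply(seq_len(spec$n_batches), function(b) {
    sel <- batch == b
    1 - sum(survives & sel) / sum(sel)
  }, numeric(1))

  list(
    differential_i = d_i[1], differential_i_se = d_i[2],
    differential_j = d_j[1], differential_j_se = d_j[2],
    degree_of_control = 1 - n_parents / n,
    degree_of_control_se = .batch_se(ctrl_batch),
    exposed_survival_i = p_i, exposed_survival_j = p_j,
    n_parents = n_parents, degenerate = FALSE
  )
}

#' Export a simulated cohort to CSV (debugging aid)
#'
#' Re-draws the cohort for the given spec and writes one row per individual
#' (trait values, exposure and survival flags).
#'
#' @param spec A [cohort_spec()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_cohort <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  mix <- !is.null(spec$efficacy_j)
  p_i <- field_survival(prs_to_bioassay(spec$mean_prs_i, spec$scale),
                        spec$efficacy_i, spec$field_params)
  p_j <- if (mix) {
    field_survival(prs_to_bioassay(spec$mean_prs_j, spec$scale),
                   spec$efficacy_j, spec$field_params)
  } else {
    NA_real_
  }
  df <- withr::with_seed(spec$seed, {
    n <- spec$n_individuals
    z_i <- stats::rnorm(n, spec$mean_prs_i, spec$sigma)
    z_j <- if (mix) stats::rnorm(n, spec$mean_prs_j, spec$sigma) else NA_real_
    exposed <- stats::runif(n) < spec$exposure
    thr_i <- if (p_i >= 1) -Inf else if (p_i <= 0) Inf else
      stats::qnorm(1 - p_i, spec$mean_prs_i, spec$sigma)
    survives <- !exposed | (z_i > thr_i)
    if (mix) {
      thr_j <- if (p_j >= 1) -Inf else if (p_j <= 0) Inf else
        stats::qnorm(1 - p_j, spec$mean_prs_j, spec$sigma)
      survives <- survives & (!exposed | (z_j > thr_j))
    }
    tibble::tibble(prs_i = z_i, prs_j = z_j, exposed = exposed,
                   survives = survives)
  })
  readr::write_csv(df, path)
  invisible(path)
}
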