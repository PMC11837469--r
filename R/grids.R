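#' Specification of a single-generation parameter sweep
#'
#' Defines the exhaustive efficacy x exposure x resistance grid over which
#' single-generation selection is evaluated. Defaults follow the standard
#' protocol: efficacies 0 to 1.2 in steps of 0.1 (13 values, spanning decayed
#' through above-recommended doses), exposures 0.1 to 1 in steps of 0.1,
#' initial resistance at 0, 5, 10, 20, 50 or 80% bioassay survival,
#' heritability 0.2, phenotypic standard deviation 20, equal male and female
#' exposure, no dispersal and no fitness costs.
#'
#' @param efficacy_values Insecticide efficacies to sweep.
#' @param exposure_values Exposure proportions to sweep.
#' @param resistance_levels Initial resistance levels, as bioassay-survival
#'   percentages in `[0, 100)`.
#' @param heritability Heritability applied to both traits.
#' @param sigma Phenotypic standard deviation of the PRS.
#' @param mode `"monotherapy"` or `"mixture"`.
#' @param beta Exposure scaling factor.
#' @param scale A [resistance_scale()].
#' @param field_params A [field_survival_params()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(efficacy_values = seq(0, 12) / 10,
                      exposure_values = seq(1, 10) / 10,
                      resistance_levels = c(0, 5, 10, 20, 50, 80),
                      heritability = 0.2, sigma = 20,
                      mode = c("monotherapy", "mixture"),
                      beta = 1,
                      scale = resistance_scale(),
                      field_params = field_survival_params()) {
  mode <- match.arg(mode)
  stopifnot(
    "efficacy values must be non-negative" =
      length(efficacy_values) > 0 && all(efficacy_values >= 0),
    "exposure values must lie in [0, 1]" =
      length(exposure_values) > 0 && all(exposure_values >= 0 & exposure_values <= 1),
    "resistance levels are bioassay-survival percentages in [0, 100)" =
      length(resistance_levels) > 0 &&
      all(resistance_levels >= 0 & resistance_levels < 100),
    "heritability must lie in [0, 1]" = heritability >= 0 && heritability <= 1,
    "sigma must be positive" = sigma > 0,
    "beta must be positive" = beta > 0,
    inherits(scale, "resistance_scale"),
    inherits(field_params, "field_survival_params")
  )
  structure(
    list(efficacy_values = efficacy_values, exposure_values = exposure_values,
         resistance_levels = resistance_levels, heritability = heritability,
         sigma = sigma, mode = mode, beta = beta, scale = scale,
         field_params = field_params),
    class = "grid_spec"
  )
}

#' Seed a population mean from a bioassay-survival level
#'
#' Inverts the Hill mapping to obtain the mean PRS corresponding to a given
#' bioassay-survival percentage. For the six standard levels (0, 5, 10, 20,
#' 50, 80%) under the default scale the conventional rounded scores
#' \{0, 47, 100, 225, 900, 3600\} are used (47 is the rounding of the exact
#' inverse 47.37); other levels use the exact inverse.
#'
#' @param bioassay_percent Bioassay survival percentage(s) in `[0, 100)`.
#' @param scale A [resistance_scale()].
#' @return Mean PRS value(s).
#' @export
seed_population <- function(bioassay_percent, scale = resistance_scale()) {
  stopifnot(is.numeric(bioassay_percent))
  if (any(bioassay_percent < 0 | bioassay_percent >= 100)) {
    stop("bioassay survival percentage must lie in [0, 100)")
  }
  z <- bioassay_to_prs(bioassay_percent / 100, scale)
  default_scale <- scale$half_saturation == 900 && scale$hill_coefficient == 1
  if (default_scale) {
    std <- c(`0` = 0, `5` = 47, `10` = 100, `20` = 225, `50` = 900, `80` = 3600)
    hit <- match(as.character(bioassay_percent), names(std))
    z <- ifelse(is.na(hit), z, std[ifelse(is.na(hit), 1L, hit)])
  }
  unname(z)
}

# Vectorised single-generation outcome for equal male/female exposure and no
# costs: p may contain raw zeros; degenerate cells (exposure 1, survival 0)
# get delta = NA. Returns delta in percentage points of bioassay survival.
.grid_delta <- function(z, p_own, p_joint, exposure, h2, sigma, beta, scale,
                        floor = 1e-10) {
  degenerate <- exposure == 1 & p_joint == 0
  p_own_f <- pmax(p_own, floor)
  p_joint_f <- pmax(p_joint, floor)
  intensity <- ifelse(p_own_f == 1, 0,
                      stats::dnorm(stats::qnorm(1 - p_own_f)) / p_own_f)
  s <- exposure * p_joint_f * sigma * intensity /
    ((1 - exposure) + exposure * p_joint_f)
  response <- h2 * s * beta  # equal exposure in both sexes: sex average = s
  delta <- 100 * (prs_to_bioassay(z + response, scale) - prs_to_bioassay(z, scale))
  delta[degenerate] <- NA_real_
  delta
}

#' Monotherapy single-generation sweep
#'
#' Runs the full efficacy x exposure x resistance grid for a single deployed
#' insecticide, reporting the single-generation change in bioassay survival
#' (percentage points) and the degree of control for every cell. Cells where
#' the whole population is exposed and no exposed mosquito survives are
#' degenerate (population extinction): their control is 1 and the change in
#' survival is recorded as `NA`.
#'
#' @param spec A [grid_spec()] with `mode = "monotherapy"`.
#' @return A tibble with one row per grid cell, ordered lexicographically by
#'   efficacy, exposure, then resistance level: columns `efficacy`,
#'   `exposure`, `resistance_i` (%), `mean_prs_i`, `exposed_survival_i`,
#'   `delta_bioassay_i` (percentage points) and `degree_of_control`.
#' @export
run_mono_grid <- function(spec = grid_spec(mode = "monotherapy")) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$mode != "monotherapy") stop("spec mode must be 'monotherapy'")
  g <- tidyr::expand_grid(
    efficacy = spec$efficacy_values,
    exposure = spec$exposure_values,
    resistance_i = spec$resistance_levels
  )
  z <- seed_population(g$resistance_i, spec$scale)
  p <- field_survival(prs_to_bioassay(z, spec$scale), g$efficacy,
                      spec$field_params)
  tibble::tibble(
    efficacy = g$efficacy,
    exposure = g$exposure,
    resistance_i = g$resistance_i,
    mean_prs_i = z,
    exposed_survival_i = p,
    delta_bioassay_i = .grid_delta(z, p, p, g$exposure, spec$heritability,
                                   spec$sigma, spec$beta, spec$scale),
    degree_of_control = degree_of_control(g$exposure, p)
  )
}

#' Mixture single-generation sweep
#'
#' Runs the full efficacy_i x efficacy_j x exposure x resistance_i x
#' resistance_j grid for a two-insecticide mixture (60,840 cells at the
#' defaults). For each cell the change in bioassay survival is reported per
#' insecticide together with their sum (the total amount of selection) and
#' the degree of control from the joint survival `p_i * p_j`.
#'
#' @param spec A [grid_spec()] with `mode = "mixture"`.
#' @return A tibble with one row per cell, ordered lexicographically by
#'   efficacy_i, efficacy_j, exposure, resistance_i, resistance_j: columns
#'   `efficacy_i`, `efficacy_j`, `exposure`, `resistance_i`, `resistance_j`,
#'   `mean_prs_i`, `mean_prs_j`, `exposed_survival_i`, `exposed_survival_j`,
#'   `delta_bioassay_i`, `delta_bioassay_j`, `delta_total` and
#'   `degree_of_control`.
#' @export
run_mixture_grid <- function(spec = grid_spec(mode = "mixture")) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$mode != "mixture") stop("spec mode must be 'mixture'")
  g <- tidyr::expand_grid(
    efficacy_i = spec$efficacy_values,
    efficacy_j = spec$efficacy_values,
    exposure = spec$exposure_values,
    resistance_i = spec$resistance_levels,
    resistance_j = spec$resistance_levels
  )
  z_i <- seed_population(g$resistance_i, spec$scale)
  z_j <- seed_population(g$resistance_j, spec$scale)
  p_i <- field_survival(prs_to_bioassay(z_i, spec$scale), g$efficacy_i,
                        spec$field_params)
  p_j <- field_survival(prs_to_bioassay(z_j, spec$scale), g$efficacy_j,
                        spec$field_params)
  joint <- p_i * p_j
  d_i <- .grid_delta(z_i, p_i, joint, g$exposure, spec$heritability,
                     spec$sigma, spec$beta, spec$scale)
  d_j <- .grid_delta(z_j, p_j, joint, g$exposure, spec$heritability,
                     spec$sigma, spec$beta, spec$scale)
  tibble::tibble(
    efficacy_i = g$efficacy_i, efficacy_j = g$efficacy_j,
    exposure = g$exposure,
    resistance_i = g$resistance_i, resistance_j = g$resistance_j,
    mean_prs_i = z_i, mean_prs_j = z_j,
    exposed_survival_i = p_i, exposed_survival_j = p_j,
    delta_bioassay_i = d_i, delta_bioassay_j = d_j,
    delta_total = d_i + d_j,
    degree_of_control = degree_of_control(g$exposure, joint)
  )
}
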