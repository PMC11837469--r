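#' Hill-type scale linking the polygenic resistance score to bioassay survival
#'
#' The polygenic resistance score (PRS) is an abstract quantitative trait
#' summarising many-locus insecticide resistance. It is made operationally
#' interpretable by mapping it onto the proportion of mosquitoes expected to
#' survive a standardised discriminating-dose bioassay (e.g. the WHO tube
#' test) via a Hill variant of the Michaelis-Menten equation,
#' \deqn{k(z) = z^n / (z^n + K^n),}
#' where \eqn{K} is the PRS at which half the population survives the
#' bioassay and \eqn{n} is the Hill coefficient. The defaults (\eqn{K = 900},
#' \eqn{n = 1}) reproduce the calibration pairs used throughout: PRS 0, 47,
#' 100, 225, 900 and 3600 correspond to 0, 5, 10, 20, 50 and 80% bioassay
#' survival.
#'
#' @param half_saturation PRS value giving 50% bioassay survival. Must be
#'   positive.
#' @param hill_coefficient Hill coefficient (steepness). Must be positive.
#' @return An object of class `resistance_scale`.
#' @examples
#' sc <- resistance_scale()
#' prs_to_bioassay(900, sc)  # 0.5
#' @export
resistance_scale <- function(half_saturation = 900, hill_coefficient = 1) {
  stopifnot(
    "half_saturation must be a single positive number" =
      is.numeric(half_saturation) && length(half_saturation) == 1 &&
      is.finite(half_saturation) && half_saturation > 0,
    "hill_coefficient must be a single positive number" =
      is.numeric(hill_coefficient) && length(hill_coefficient) == 1 &&
      is.finite(hill_coefficient) && hill_coefficient > 0
  )
  structure(
    list(half_saturation = half_saturation,
         hill_coefficient = hill_coefficient),
    class = "resistance_scale"
  )
}

#' Regression constants linking bioassay survival to field survival
#'
#' Survival in a standardised bioassay overstates mortality in the field,
#' where contact times vary. Expected field survival of exposed mosquitoes
#' under a fully effective insecticide is modelled as the linear regression
#' `phi1 * bioassay_survival + phi2`; [field_survival()] further adjusts for
#' the insecticide's current efficacy.
#'
#' @param phi1 Regression slope (dimensionless, default 0.48).
#' @param phi2 Regression intercept: field survival of a fully susceptible
#'   population under a fully effective insecticide (default 0.15).
#' @return An object of class `field_survival_params`.
#' @export
field_survival_params <- function(phi1 = 0.48, phi2 = 0.15) {
  stopifnot(
    "phi1 must be a single non-negative number" =
      is.numeric(phi1) && length(phi1) == 1 && is.finite(phi1) && phi1 >= 0,
    "phi2 must be a single number in [0, 1)" =
      is.numeric(phi2) && length(phi2) == 1 && phi2 >= 0 && phi2 < 1,
    "phi1 + phi2 must not exceed 1" = phi1 + phi2 <= 1
  )
  structure(list(phi1 = phi1, phi2 = phi2), class = "field_survival_params")
}

#' Convert a polygenic resistance score to bioassay survival
#'
#' Applies the Hill mapping `max(0, z)^n / (max(0, z)^n + K^n)`. Negative
#' scores are permitted as state values (a susceptibility reserve) but map to
#' zero survival. The output is strictly below 1 for finite scores.
#'
#' @param z Polygenic resistance score(s); any real number, vectorised.
#' @param scale A [resistance_scale()].
#' @return Bioassay survival proportion(s) in `[0, 1)`.
#' @examples
#' prs_to_bioassay(c(0, 225, 900, 3600))  # 0, 0.2, 0.5, 0.8
#' @export
prs_to_bioassay <- function(z, scale = resistance_scale()) {
  stopifnot(inherits(scale, "resistance_scale"), is.numeric(z))
  zc <- pmax(0, z)^scale$hill_coefficient
  zc / (zc + scale$half_saturation^scale$hill_coefficient)
}

#' Convert bioassay survival to the polygenic resistance score
#'
#' Inverse of [prs_to_bioassay()]: `K * (k / (1 - k))^(1/n)`. Survival of
#' 100% has no finite score, so `k` must lie in `[0, 1)`.
#'
#' @param k Bioassay survival proportion(s) in `[0, 1)`, vectorised.
#' @param scale A [resistance_scale()].
#' @return Polygenic resistance score(s), non-negative.
#' @export
bioassay_to_prs <- function(k, scale = resistance_scale()) {
  stopifnot(inherits(scale, "resistance_scale"), is.numeric(k))
  if (any(k < 0 | k >= 1)) {
    stop("bioassay survival must lie in [0, 1): survival of 100% has no finite resistance score")
  }
  scale$half_saturation * (k / (1 - k))^(1 / scale$hill_coefficient)
}

#' Expected field survival of exposed mosquitoes
#'
#' Converts bioassay survival to expected survival of insecticide-exposed
#' mosquitoes in the field, given the insecticide's current efficacy
#' \eqn{\omega}:
#' \deqn{p = 1 - \omega (1 - (\phi_1 k + \phi_2)),}
#' clamped to `[0, 1]`. At \eqn{\omega = 1} this reduces to the plain
#' bioassay-to-field regression \eqn{\phi_1 k + \phi_2}; at \eqn{\omega = 0}
#' nothing is killed; efficacies above 1 (doses above the susceptible LD100)
#' can drive survival of susceptibles to zero.
#'
#' @param k_bioassay Bioassay survival proportion(s) in `[0, 1)`.
#' @param efficacy Current insecticide efficacy \eqn{\omega \ge 0};
#'   vectorised, recycled against `k_bioassay`.
#' @param params A [field_survival_params()].
#' @return Field survival proportion(s) in `[0, 1]`.
#' @examples
#' field_survival(0, 1)    # 0.15: susceptibles under a fresh insecticide
#' field_survival(0.5, 1)  # 0.39
#' @export
field_survival <- function(k_bioassay, efficacy,
                           params = field_survival_params()) {
  stopifnot(inherits(params, "field_survival_params"),
            is.numeric(k_bioassay), is.numeric(efficacy))
  if (any(k_bioassay < 0 | k_bioassay >= 1)) {
    stop("bioassay survival must lie in [0, 1)")
  }
  if (any(efficacy < 0)) stop("insecticide efficacy must be non-negative")
  pmin(1, pmax(0, 1 - efficacy * (1 - (params$phi1 * k_bioassay + params$phi2))))
}
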