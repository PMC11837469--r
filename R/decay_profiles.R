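#' Insecticide decay profile
#'
#' Efficacy of a deployed insecticide declines with time since deployment.
#' Three modes are supported:
#' * `"two_stage"` (default): a slow linear decline at `base_rate` for the
#'   first `threshold_generation` generations (insecticide chemistry), then a
#'   rapid linear decline at `rapid_rate` (fabric integrity failing), floored
#'   at zero. This is the long-lasting insecticidal net (LLIN) pattern, with
#'   defaults estimated from field durability data: base rate 0.015 efficacy
#'   per generation for 15 generations (~1.5 years), then 0.08 per
#'   generation.
#' * `"constant"`: a single linear rate throughout.
#' * `"none"`: efficacy stays at the deployed value.
#'
#' Rates are in efficacy units per generation (linear, not proportional).
#' A reduced-dose deployment is represented by lowering `deployed_efficacy`
#' (e.g. 0.75 or 0.5) with unchanged rates.
#'
#' @param deployed_efficacy Efficacy at deployment, omega0 (>= 0; 1 = the
#'   recommended dose kills all susceptibles in a bioassay).
#' @param base_rate Efficacy lost per generation during the first stage.
#' @param threshold_generation Last generation of the first stage.
#' @param rapid_rate Efficacy lost per generation after the first stage.
#' @param mode One of `"two_stage"`, `"constant"`, `"none"`.
#' @param constant_rate Efficacy lost per generation in `"constant"` mode.
#' @return An object of class `decay_profile`.
#' @examples
#' pr <- decay_profile(deployed_efficacy = 1, base_rate = 0.015)
#' efficacy_at(pr, c(0, 15, 20))  # 1, 0.775, 0.375
#' @export
decay_profile <- function(deployed_efficacy = 1, base_rate = 0.015,
                          threshold_generation = 15, rapid_rate = 0.08,
                          mode = c("two_stage", "constant", "none"),
                          constant_rate = base_rate) {
  mode <- match.arg(mode)
  stopifnot(
    "deployed_efficacy must be a single non-negative number" =
      is.numeric(deployed_efficacy) && length(deployed_efficacy) == 1 &&
      deployed_efficacy >= 0,
    "decay rates must be non-negative" =
      all(c(base_rate, rapid_rate, constant_rate) >= 0),
    "threshold_generation must be non-negative" =
      is.numeric(threshold_generation) && threshold_generation >= 0
  )
  structure(
    list(deployed_efficacy = deployed_efficacy, base_rate = base_rate,
         threshold_generation = threshold_generation, rapid_rate = rapid_rate,
         mode = mode, constant_rate = constant_rate),
    class = "decay_profile"
  )
}

#' Current efficacy of a deployed insecticide
#'
#' Evaluates the decay profile `tau` generations after (re)deployment.
#' `efficacy_at(profile, 0)` always returns the deployed efficacy, so a
#' redeployment resets decay regardless of history. The base rate applies
#' through `threshold_generation` inclusive; the rapid rate strictly after.
#'
#' @param profile A [decay_profile()].
#' @param tau Generations since deployment (integer-valued, >= 0;
#'   vectorised).
#' @return Efficacy value(s) in `[0, deployed_efficacy]`, non-increasing in
#'   `tau`.
#' @export
efficacy_at <- function(profile, tau) {
  stopifnot(inherits(profile, "decay_profile"), is.numeric(tau))
  if (any(tau < 0)) stop("generations since deployment must be non-negative")
  w0 <- profile$deployed_efficacy
  switch(
    profile$mode,
    none = rep(w0, length(tau)),
    constant = pmax(0, w0 - profile$constant_rate * tau),
    two_stage = pmax(0, w0 -
                       profile$base_rate * pmin(tau, profile$threshold_generation) -
                       profile$rapid_rate * pmax(0, tau - profile$threshold_generation))
  )
}
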