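#' Population state: mean polygenic resistance scores
#'
#' The model tracks only the mean of the polygenic resistance score (PRS)
#' for each insecticide trait; the phenotypic standard deviation is held
#' fixed across generations (default 20 PRS units).
#'
#' @param mean_prs_i Mean PRS for the trait conferring resistance to
#'   insecticide i.
#' @param mean_prs_j Mean PRS for the trait conferring resistance to
#'   insecticide j, or `NULL` for a one-trait (monotherapy-only) setting.
#' @param sigma Phenotypic standard deviation of the PRS, shared by both
#'   traits. Must be positive.
#' @return An object of class `population_state`.
#' @export
population_state <- function(mean_prs_i, mean_prs_j = NULL, sigma = 20) {
  stopifnot(
    "mean_prs_i must be a single finite number" =
      is.numeric(mean_prs_i) && length(mean_prs_i) == 1 && is.finite(mean_prs_i),
    "sigma must be a single positive number" =
      is.numeric(sigma) && length(sigma) == 1 && is.finite(sigma) && sigma > 0
  )
  if (!is.null(mean_prs_j)) {
    stopifnot("mean_prs_j must be a single finite number" =
                is.numeric(mean_prs_j) && length(mean_prs_j) == 1 &&
                is.finite(mean_prs_j))
  }
  structure(
    list(mean_prs_i = mean_prs_i, mean_prs_j = mean_prs_j, sigma = sigma),
    class = "population_state"
  )
}

#' Exposure configuration
#'
#' @param female_exposure Proportion x of adult females contacting the
#'   deployed insecticide(s) each generation.
#' @param male_ratio Male exposure as a multiple m of female exposure
#'   (male exposure is `m * x`, which must stay within `[0, 1]`).
#' @param coverage Proportion C of the population in the treated site (used
#'   by the multi-generation simulator only).
#' @param dispersal Per-generation dispersal proportion theta between demes
#'   (multi-generation simulator only).
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(female_exposure = 0.7, male_ratio = 1,
                            coverage = 0.7, dispersal = 0.2) {
  stopifnot(
    "female_exposure must lie in [0, 1]" =
      is.numeric(female_exposure) && length(female_exposure) == 1 &&
      female_exposure >= 0 && female_exposure <= 1,
    "male_ratio must be non-negative" =
      is.numeric(male_ratio) && length(male_ratio) == 1 && male_ratio >= 0,
    "male exposure (male_ratio * female_exposure) must lie in [0, 1]" =
      male_ratio * female_exposure >= 0 && male_ratio * female_exposure <= 1,
    "coverage must lie in [0, 1]" =
      is.numeric(coverage) && length(coverage) == 1 && coverage >= 0 && coverage <= 1,
    "dispersal must lie in [0, 1]" =
      is.numeric(dispersal) && length(dispersal) == 1 && dispersal >= 0 && dispersal <= 1
  )
  structure(
    list(female_exposure = female_exposure, male_ratio = male_ratio,
         coverage = coverage, dispersal = dispersal),
    class = "exposure_config"
  )
}

#' Quantitative-genetic model parameters
#'
#' Heritabilities, cross-resistance, fitness-cost differentials and the
#' exposure scaling factor used by the Breeder's-equation response, plus the
#' PRS/bioassay/field conversion constants.
#'
#' @param h2_i,h2_j Heritabilities of the two resistance traits, in `[0, 1]`.
#' @param cross_resistance Genetic correlation alpha between the two traits,
#'   in `[-1, 1]`; drives the correlated response.
#' @param exposure_scaling Multiplier beta on the response, used to calibrate
#'   simulated timescales (default 1).
#' @param cost_female_i,cost_male_i,cost_female_j,cost_male_j Fitness-cost
#'   selection differentials (PRS units, default 0) subtracted from the
#'   insecticide-selection differential of each sex and trait each
#'   generation.
#' @param field_params A [field_survival_params()].
#' @param scale A [resistance_scale()].
#' @param survival_floor Field survival is clamped up to this floor before
#'   computing the selection intensity, to avoid overflow in the truncated
#'   normal tail mean at vanishing survival.
#' @return An object of class `model_params`.
#' @export
model_params <- function(h2_i = 0.2, h2_j = 0.2, cross_resistance = 0,
                         exposure_scaling = 1,
                         cost_female_i = 0, cost_male_i = 0,
                         cost_female_j = 0, cost_male_j = 0,
                         field_params = field_survival_params(),
                         scale = resistance_scale(),
                         survival_floor = 1e-10) {
  stopifnot(
    "heritabilities must lie in [0, 1]" =
      all(c(h2_i, h2_j) >= 0) && all(c(h2_i, h2_j) <= 1),
    "cross_resistance must lie in [-1, 1]" =
      is.numeric(cross_resistance) && abs(cross_resistance) <= 1,
    "exposure_scaling must be positive" =
      is.numeric(exposure_scaling) && exposure_scaling > 0,
    "cost differentials must be finite numbers" =
      all(is.finite(c(cost_female_i, cost_male_i, cost_female_j, cost_male_j))),
    "survival_floor must lie in (0, 1)" =
      is.numeric(survival_floor) && survival_floor > 0 && survival_floor < 1,
    inherits(field_params, "field_survival_params"),
    inherits(scale, "resistance_scale")
  )
  structure(
    list(h2_i = h2_i, h2_j = h2_j, cross_resistance = cross_resistance,
         exposure_scaling = exposure_scaling,
         cost_female_i = cost_female_i, cost_male_i = cost_male_i,
         cost_female_j = cost_female_j, cost_male_j = cost_male_j,
         field_params = field_params, scale = scale,
         survival_floor = survival_floor),
    class = "model_params"
  )
}

#' Selection intensity of truncation selection
#'
#' Under truncation selection exactly the top-p fraction of a normally
#' distributed trait survives. The mean trait value of the survivors exceeds
#' the population mean by `sigma * i(p)`, where the selection intensity
#' \deqn{i(p) = \phi(\Phi^{-1}(1 - p)) / p}
#' is the mean of the upper-p tail of the standard normal (density at the
#' truncation point divided by the surviving mass). `i(1) = 0` (no
#' selection); `i` grows without bound as `p` shrinks.
#'
#' @param p Survival proportion(s) in `(0, 1]`, vectorised. Values below
#'   `floor` are clamped up to it.
#' @param floor Lower clamp for `p` (default `1e-10`).
#' @return Selection intensity (standard-deviation units).
#' @examples
#' selection_intensity(0.5)   # 0.7978846 = dnorm(0) / 0.5
#' selection_intensity(0.05)  # 2.062713
#' @export
selection_intensity <- function(p, floor = 1e-10) {
  stopifnot(is.numeric(p), is.numeric(floor), floor > 0, floor < 1)
  if (any(p <= 0)) stop("survival proportion must be positive")
  if (any(p > 1)) stop("survival proportion must not exceed 1")
  p <- pmax(p, floor)
  ifelse(p == 1, 0, stats::dnorm(stats::qnorm(1 - p)) / p)
}

# Shared kernel: selection differential on one trait, given that trait's own
# field survival p_own and the joint exposed survival p_joint (equal to p_own
# for monotherapy, p_i * p_j for a mixture). Vectorised over all arguments.
# S = x * p_joint * sigma * i(p_own) / ((1 - x) + x * p_joint):
# exposed survivors carry a mean excess of sigma * i(p_own) and make up a
# fraction x * p_joint of the parental pool, diluted by the (1 - x) unexposed.
.differential_kernel <- function(p_own, p_joint, exposure, sigma, floor) {
  if (any(exposure == 1 & p_joint == 0)) {
    stop("degenerate extinction: full exposure with zero exposed survival kills the entire population")
  }
  p_own_f <- pmax(p_own, floor)
  p_joint_f <- pmax(p_joint, floor)
  intensity <- ifelse(p_own_f == 1, 0, stats::dnorm(stats::qnorm(1 - p_own_f)) / p_own_f)
  num <- exposure * p_joint_f * sigma * intensity
  den <- (1 - exposure) + exposure * p_joint_f  # never 0: exposure = 0 gives den = 1
  num / den
}

#' Monotherapy selection differential
#'
#' Within-generation change in the mean PRS of one trait when a single
#' insecticide is deployed. Exposed mosquitoes undergo truncation selection
#' with survival `p = field_survival(prs_to_bioassay(mean), efficacy)`; the
#' parental pool is the exposed survivors diluted by the unexposed fraction:
#' \deqn{S = \frac{x\, p\, \sigma\, i(p)}{(1 - x) + x p}.}
#'
#' @param state A [population_state()].
#' @param trait `"i"` or `"j"`: which trait the insecticide selects on.
#' @param efficacy Current insecticide efficacy (vectorised).
#' @param exposure Proportion exposed (vectorised, recycled).
#' @param params A [model_params()].
#' @return A list with `differential` (PRS units) and `exposed_survival`
#'   (field survival among exposed).
#' @export
mono_selection_differential <- function(state, trait = "i", efficacy, exposure,
                                        params = model_params()) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_params"),
            trait %in% c("i", "j"))
  zbar <- if (trait == "i") state$mean_prs_i else state$mean_prs_j
  if (is.null(zbar)) stop("state has no trait '", trait, "'")
  p <- field_survival(prs_to_bioassay(zbar, params$scale), efficacy,
                      params$field_params)
  list(
    differential = .differential_kernel(p, p, exposure, state$sigma,
                                        params$survival_floor),
    exposed_survival = p
  )
}

#' Mixture selection differentials
#'
#' With two insecticides in one formulation, an exposed mosquito must survive
#' both truncations: its trait-i value must clear the trait-i threshold
#' (survival `p_i`) and its trait-j value the trait-j threshold (`p_j`).
#' The traits are phenotypically independent given the means, so joint
#' exposed survival is `p_i * p_j` and survivors' mean excess on trait i is
#' still `sigma * i(p_i)`:
#' \deqn{S_i = \frac{x\, p_i p_j\, \sigma\, i(p_i)}{(1 - x) + x p_i p_j},}
#' symmetrically for trait j. An effective partner thus shrinks the weight of
#' trait-i-selected survivors in the parental pool (mutual protection); at
#' full exposure there is no unexposed dilution and `S_i` is independent of
#' the partner.
#'
#' @param state A two-trait [population_state()].
#' @param efficacy_i,efficacy_j Current efficacies of the two insecticides
#'   (vectorised, recycled).
#' @param exposure Proportion exposed to the mixture.
#' @param params A [model_params()].
#' @return A list with `differential_i`, `differential_j` (PRS units) and
#'   `exposed_survival_i`, `exposed_survival_j` (per-insecticide field
#'   survival among exposed).
#' @export
mixture_selection_differentials <- function(state, efficacy_i, efficacy_j,
                                            exposure,
                                            params = model_params()) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_params"))
  if (is.null(state$mean_prs_j)) {
    stop("mixture deployment needs a two-trait population state")
  }
  p_i <- field_survival(prs_to_bioassay(state$mean_prs_i, params$scale),
                        efficacy_i, params$field_params)
  p_j <- field_survival(prs_to_bioassay(state$mean_prs_j, params$scale),
                        efficacy_j, params$field_params)
  joint <- p_i * p_j
  list(
    differential_i = .differential_kernel(p_i, joint, exposure, state$sigma,
                                          params$survival_floor),
    differential_j = .differential_kernel(p_j, joint, exposure, state$sigma,
                                          params$survival_floor),
    exposed_survival_i = p_i,
    exposed_survival_j = p_j
  )
}

#' Breeder's-equation response to selection
#'
#' The between-generation change in the mean PRS of one trait:
#' \deqn{R = h^2 \cdot \frac{S_f + S_m}{2} \cdot \beta,}
#' the sex-averaged selection differential scaled by heritability and the
#' exposure scaling factor beta.
#'
#' @param diff_female,diff_male Sex-specific selection differentials (PRS
#'   units).
#' @param h2 Heritability of the trait.
#' @param beta Exposure scaling factor.
#' @return Response to selection (PRS units).
#' @examples
#' breeders_response(10, 10, h2 = 0.2, beta = 1)  # 2
#' @export
breeders_response <- function(diff_female, diff_male, h2, beta = 1) {
  stopifnot(is.numeric(diff_female), is.numeric(diff_male),
            all(h2 >= 0 & h2 <= 1), all(beta > 0))
  h2 * (diff_female + diff_male) / 2 * beta
}

#' Add the correlated response from cross-resistance
#'
#' Cross-resistance between the two traits (genetic correlation alpha) adds
#' a correlated response in the standard Falconer form, with equal phenotypic
#' standard deviations for the two traits:
#' \deqn{R_i^{tot} = R_i + \alpha \sqrt{h_I^2 h_J^2}\; \bar S_j\, \beta,}
#' where \eqn{\bar S_j} is the sex-averaged selection differential on the
#' partner trait; symmetrically for trait j.
#'
#' @param response_direct_i,response_direct_j Direct Breeder's-equation
#'   responses (PRS units).
#' @param mean_diff_i,mean_diff_j Sex-averaged selection differentials (PRS
#'   units).
#' @param params A [model_params()] supplying alpha, the heritabilities and
#'   beta.
#' @return A list with `total_response_i` and `total_response_j`.
#' @export
apply_cross_resistance <- function(response_direct_i, response_direct_j,
                                   mean_diff_i, mean_diff_j,
                                   params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  co <- params$cross_resistance * sqrt(params$h2_i * params$h2_j) *
    params$exposure_scaling
  list(
    total_response_i = response_direct_i + co * mean_diff_j,
    total_response_j = response_direct_j + co * mean_diff_i
  )
}

#' Degree of control over a single generation
#'
#' The proportion of the adult female population killed by the deployed
#' insecticide(s) within one generation:
#' \deqn{1 - [(1 - x) + x\, p] = x (1 - p),}
#' where `x` is female exposure and `p` the joint field survival of exposed
#' females (per-insecticide survival for monotherapy, the product for a
#' mixture). A value of 1 means every female is killed; 0 means the
#' intervention has no effect.
#'
#' @param exposure Female exposure proportion (vectorised).
#' @param joint_exposed_survival Field survival of exposed females.
#' @return Degree of control in `[0, 1]`.
#' @export
degree_of_control <- function(exposure, joint_exposed_survival) {
  stopifnot(all(exposure >= 0 & exposure <= 1),
            all(joint_exposed_survival >= 0 & joint_exposed_survival <= 1))
  exposure * (1 - joint_exposed_survival)
}

#' Deployment descriptors
#'
#' @param trait Which trait a monotherapy selects on (`"i"` or `"j"`).
#' @param efficacy,efficacy_i,efficacy_j Current insecticide efficacies.
#' @return A deployment description for [single_generation_step()].
#' @export
monotherapy <- function(trait = "i", efficacy = 1) {
  stopifnot(trait %in% c("i", "j"), is.numeric(efficacy), efficacy >= 0)
  structure(list(kind = "monotherapy", trait = trait, efficacy = efficacy),
            class = "deployment")
}

#' @rdname monotherapy
#' @export
mixture <- function(efficacy_i = 1, efficacy_j = 1) {
  stopifnot(is.numeric(efficacy_i), efficacy_i >= 0,
            is.numeric(efficacy_j), efficacy_j >= 0)
  structure(list(kind = "mixture", efficacy_i = efficacy_i,
                 efficacy_j = efficacy_j),
            class = "deployment")
}

#' Advance one generation of insecticide selection
#'
#' Composes the full single-generation update: sex-specific selection
#' differentials (females exposed at `x`, males at `m * x`), subtraction of
#' fitness-cost differentials, sex-averaging, the Breeder's-equation
#' response, the correlated (cross-resistance) response, and the update of
#' the mean PRS. The degree of control is reported from female exposure.
#'
#' @param state A [population_state()].
#' @param deployment A [monotherapy()] or [mixture()] descriptor, or `NULL`
#'   for no insecticide (fitness costs, if any, still act).
#' @param exposure An [exposure_config()].
#' @param params A [model_params()].
#' @return A list with `state` (the updated [population_state()]) and
#'   `outcome`, a list holding the sex-specific differentials, total
#'   responses, exposed survivals and the degree of control.
#' @export
single_generation_step <- function(state, deployment, exposure,
                                   params = model_params()) {
  stopifnot(inherits(state, "population_state"),
            inherits(exposure, "exposure_config"),
            inherits(params, "model_params"))
  if (!is.null(deployment) && !inherits(deployment, "deployment")) {
    stop("deployment must be monotherapy(), mixture() or NULL")
  }
  x_f <- exposure$female_exposure
  x_m <- exposure$male_ratio * x_f
  two_trait <- !is.null(state$mean_prs_j)

  s_f <- c(i = 0, j = 0)
  s_m <- c(i = 0, j = 0)
  surv <- c(i = 1, j = 1)
  joint <- 1
  if (!is.null(deployment) && deployment$kind == "monotherapy") {
    tr <- deployment$trait
    f <- mono_selection_differential(state, tr, deployment$efficacy, x_f, params)
    m <- mono_selection_differential(state, tr, deployment$efficacy, x_m, params)
    s_f[tr] <- f$differential
    s_m[tr] <- m$differential
    surv[tr] <- f$exposed_survival
    joint <- f$exposed_survival
  } else if (!is.null(deployment) && deployment$kind == "mixture") {
    f <- mixture_selection_differentials(state, deployment$efficacy_i,
                                         deployment$efficacy_j, x_f, params)
    m <- mixture_selection_differentials(state, deployment$efficacy_i,
                                         deployment$efficacy_j, x_m, params)
    s_f[] <- c(f$differential_i, f$differential_j)
    s_m[] <- c(m$differential_i, m$differential_j)
    surv[] <- c(f$exposed_survival_i, f$exposed_survival_j)
    joint <- f$exposed_survival_i * f$exposed_survival_j
  }

  # fitness costs subtract from the differential in both sexes
  d_f <- c(i = s_f[["i"]] - params$cost_female_i,
           j = s_f[["j"]] - params$cost_female_j)
  d_m <- c(i = s_m[["i"]] - params$cost_male_i,
           j = s_m[["j"]] - params$cost_male_j)
  mean_diff <- (d_f + d_m) / 2

  resp_i <- breeders_response(d_f[["i"]], d_m[["i"]], params$h2_i,
                              params$exposure_scaling)
  resp_j <- breeders_response(d_f[["j"]], d_m[["j"]], params$h2_j,
                              params$exposure_scaling)
  if (two_trait) {
    tot <- apply_cross_resistance(resp_i, resp_j,
                                  mean_diff[["i"]], mean_diff[["j"]], params)
  } else {
    tot <- list(total_response_i = resp_i, total_response_j = NULL)
  }

  new_state <- population_state(
    mean_prs_i = state$mean_prs_i + tot$total_response_i,
    mean_prs_j = if (two_trait) state$mean_prs_j + tot$total_response_j,
    sigma = state$sigma
  )
  outcome <- list(
    differential_female_i = d_f[["i"]], differential_male_i = d_m[["i"]],
    differential_female_j = d_f[["j"]], differential_male_j = d_m[["j"]],
    response_i = tot$total_response_i,
    response_j = tot$total_response_j,
    exposed_survival_i = surv[["i"]], exposed_survival_j = surv[["j"]],
    degree_of_control = degree_of_control(x_f, joint)
  )
  list(state = new_state, outcome = outcome)
}
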