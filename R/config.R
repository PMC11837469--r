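#' Default run configuration
#'
#' The full nested configuration with every parameter at its default value:
#' Hill scale (half-saturation 900, coefficient 1), bioassay-to-field
#' regression (0.48, 0.15), heritabilities 0.2, no cross-resistance, exposure
#' scaling 1, zero fitness costs, female exposure 0.7 with equal male
#' exposure, coverage 0.7, dispersal 0.2, two-stage decay (base 0.015 for 15
#' generations then 0.08) from deployed efficacy 1 for both insecticides,
#' the standard single-generation grid, and the standard strategy settings
#' (withdrawal 10%, return 8%, redeployment every 30 generations, 500
#' generation cap at 10 generations per year).
#'
#' @return A named nested list of class `irmsim_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "results",
    scale = list(half_saturation = 900, hill_coefficient = 1),
    field = list(phi1 = 0.48, phi2 = 0.15),
    model = list(h2_i = 0.2, h2_j = 0.2, cross_resistance = 0,
                 exposure_scaling = 1,
                 cost_female_i = 0, cost_male_i = 0,
                 cost_female_j = 0, cost_male_j = 0,
                 survival_floor = 1e-10),
    exposure = list(female_exposure = 0.7, male_ratio = 1,
                    coverage = 0.7, dispersal = 0.2),
    decay_i = list(deployed_efficacy = 1, base_rate = 0.015,
                   threshold_generation = 15, rapid_rate = 0.08,
                   mode = "two_stage", constant_rate = 0.015),
    decay_j = list(deployed_efficacy = 1, base_rate = 0.015,
                   threshold_generation = 15, rapid_rate = 0.08,
                   mode = "two_stage", constant_rate = 0.015),
    grid = list(efficacy_values = seq(0, 12) / 10,
                exposure_values = seq(1, 10) / 10,
                resistance_levels = c(0, 5, 10, 20, 50, 80),
                heritability = 0.2, sigma = 20, mode = "monotherapy",
                beta = 1),
    strategy = list(strategy = "sequence",
                    initial_means = c(0, 0), sigma = 20,
                    withdrawal_threshold = 10, return_threshold = 8,
                    deployment_frequency = 30, max_generations = 500,
                    generations_per_year = 10,
                    mixture_deployed_efficacy = NULL,
                    monitor = "site")
  ), class = "irmsim_config")
}

# recursive merge of user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("configuration section '", paste(path, collapse = "$"),
         "' must be a mapping")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key: ",
         paste(c(path, unknown[1]), collapse = "$"))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration, fills every
#' missing value with the defaults of [default_config()], rejects unknown
#' keys (naming the offending key), and validates all constraints by
#' constructing the corresponding parameter objects. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration of class `irmsim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config <- .merge_config(unclass(default_config()), user)
  config <- structure(config, class = "irmsim_config")
  validate_config(config)
  config
}

#' Validate a run configuration
#'
#' Builds every parameter object implied by the configuration so that all
#' constructor invariants are checked, plus cross-field constraints (e.g.
#' the return threshold must sit below the withdrawal threshold).
#'
#' @param config An `irmsim_config` list.
#' @return The config, invisibly; errors name the violated constraint.
#' @export
validate_config <- function(config) {
  as_model_params(config)
  as_grid_spec(config)
  as_strategy_config(config)
  invisible(config)
}

#' Build parameter objects from a configuration
#'
#' @param config An `irmsim_config` list (see [default_config()]).
#' @return `as_model_params()` a [model_params()]; `as_exposure_config()` an
#'   [exposure_config()]; `as_decay_profiles()` a list of two
#'   [decay_profile()]s; `as_grid_spec()` a [grid_spec()];
#'   `as_strategy_config()` a [strategy_config()].
#' @export
as_model_params <- function(config) {
  m <- config$model
  model_params(
    h2_i = m$h2_i, h2_j = m$h2_j, cross_resistance = m$cross_resistance,
    exposure_scaling = m$exposure_scaling,
    cost_female_i = m$cost_female_i, cost_male_i = m$cost_male_i,
    cost_female_j = m$cost_female_j, cost_male_j = m$cost_male_j,
    field_params = field_survival_params(config$field$phi1, config$field$phi2),
    scale = resistance_scale(config$scale$half_saturation,
                             config$scale$hill_coefficient),
    survival_floor = m$survival_floor
  )
}

#' @rdname as_model_params
#' @export
as_exposure_config <- function(config) {
  e <- config$exposure
  exposure_config(female_exposure = e$female_exposure,
                  male_ratio = e$male_ratio,
                  coverage = e$coverage, dispersal = e$dispersal)
}

#' @rdname as_model_params
#' @export
as_decay_profiles <- function(config) {
  build <- function(d) {
    decay_profile(deployed_efficacy = d$deployed_efficacy,
                  base_rate = d$base_rate,
                  threshold_generation = d$threshold_generation,
                  rapid_rate = d$rapid_rate, mode = d$mode,
                  constant_rate = d$constant_rate)
  }
  list(decay_i = build(config$decay_i), decay_j = build(config$decay_j))
}

#' @rdname as_model_params
#' @export
as_grid_spec <- function(config) {
  g <- config$grid
  grid_spec(
    efficacy_values = g$efficacy_values, exposure_values = g$exposure_values,
    resistance_levels = g$resistance_levels, heritability = g$heritability,
    sigma = g$sigma, mode = g$mode, beta = g$beta,
    scale = resistance_scale(config$scale$half_saturation,
                             config$scale$hill_coefficient),
    field_params = field_survival_params(config$field$phi1, config$field$phi2)
  )
}

#' @rdname as_model_params
#' @export
as_strategy_config <- function(config) {
  s <- config$strategy
  profiles <- as_decay_profiles(config)
  strategy_config(
    strategy = s$strategy,
    decay_i = profiles$decay_i, decay_j = profiles$decay_j,
    params = as_model_params(config),
    exposure = as_exposure_config(config),
    initial_means = s$initial_means, sigma = s$sigma,
    withdrawal_threshold = s$withdrawal_threshold,
    return_threshold = s$return_threshold,
    deployment_frequency = s$deployment_frequency,
    max_generations = s$max_generations,
    generations_per_year = s$generations_per_year,
    mixture_deployed_efficacy = s$mixture_deployed_efficacy,
    monitor = s$monitor
  )
}

#' Write a configuration to YAML
#'
#' @param config An `irmsim_config` list.
#' @param path Output path (`.yaml`).
#' @return The path, invisibly. A write-then-[load_config()] round trip
#'   returns an identical configuration.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a results table as CSV with a metadata header
#'
#' Prepends commented metadata lines (`# key: value`) recording the package
#' version, a hash of the generating configuration or spec, the seed and any
#' extra fields, then the CSV body ('.' decimal, comma delimiter, header
#' row, no index column). Rerunning with the same inputs gives a
#' byte-identical file.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param meta Named list of metadata values; list elements are hashed, and
#'   scalars are recorded verbatim.
#' @return The path, invisibly.
#' @export
write_results_csv <- function(df, path, meta = list()) {
  stopifnot(is.data.frame(df))
  meta <- c(list(package = "irmsim",
                 version = as.character(utils::packageVersion("irmsim"))),
            meta)
  lines <- vapply(names(meta), function(nm) {
    val <- meta[[nm]]
    if (is.list(val) || length(val) > 1) val <- rlang::hash(val)
    sprintf("# %s: %s", nm, as.character(val))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  readr::write_csv(df, con)
  invisible(path)
}

#' Read a results table written by [write_results_csv()]
#'
#' @param path Path to the CSV.
#' @return A tibble (metadata lines are skipped).
#' @export
read_results_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
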