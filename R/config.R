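## Structured config files (YAML): a flat key-value `model` section holding
## the population PK parameters, plus optional `regimens` and `population`
## sections. Every packaged default is overridable.

#' Read and write model configuration files
#'
#' The `model` section is a flat key-value map of [pop_parameters()] fields
#' and round-trips exactly. Optional sections: `regimens` (named entries with
#' `formulation`, `dose_per_kg`, `interval`, `horizon`, `first_dose_time`)
#' and `population` (covariate distribution overrides merged over
#' [default_covariate_params()]).
#'
#' @param params An [pop_parameters()] object.
#' @param path File path (YAML).
#' @param regimens Optional named list of [regimen()] objects to store.
#' @param population Optional covariate parameter list to store.
#' @return [read_model_config()] returns a list with elements `model`
#'   (an `igsim_parameters`), `regimens` (named list of `igsim_regimen` or
#'   `NULL`) and `population` (merged covariate parameters).
#' @export
write_model_config <- function(params, path, regimens = NULL, population = NULL) {
  cfg <- list(model = lapply(unclass(params), identity))
  if (!is.null(regimens)) cfg$regimens <- lapply(regimens, unclass)
  if (!is.null(population)) cfg$population <- population
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stopf("config file %s has no `model` section", path)
  params <- do.call(pop_parameters, cfg$model)
  regimens <- NULL
  if (!is.null(cfg$regimens)) {
    regimens <- lapply(cfg$regimens, function(r) do.call(regimen, r))
  }
  population <- modify_list(default_covariate_params(), cfg$population)
  list(model = params, regimens = regimens, population = population)
}

## Recursive list merge (overrides win).
modify_list <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Packaged (calibrated) default parameters
#'
#' The parameter set shipped with the package, produced by running
#' [calibrate_defaults()] from [reference_parameters()] against the published
#' stratum-level trough anchors.
#'
#' @return An `igsim_parameters` object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "model_defaults.yaml", package = "igsim")
  if (!nzchar(path)) stopf("packaged default config not found")
  read_model_config(path)$model
}

## Stable hash of a parameter set for provenance records.
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(unclass(params), digits = NA, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a provenance record
#'
#' JSON record of the seed, switch concentration, grid step, parameter hash
#' and package version of a scenario run.
#'
#' @param result An `igsim_scenario`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(result, path) {
  jsonlite::write_json(result$provenance, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
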