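#' Read and write model specifications as YAML
#'
#' The on-disk schema holds the declarative parts of a model: `states`,
#' `initial_conditions`, `unknown_ics`, `output_map`, `extracellular`,
#' `dilution_rate`, `parameters`, `stoichiometry` (rate -> signed state
#' coefficients) and `rate_laws`. A rate law is stored as the string
#' `"default"` (generic Michaelis-Menten in the consumed states) or as a
#' registry key that `read_kinetic_model()` resolves against the
#' `rate_registry` argument — arbitrary R closures are not serialized.
#'
#' @param model A [kinetic_model()] whose rate laws are all `"default"`.
#' @param path File path.
#' @param rate_registry Named list of rate functions used to resolve
#'   non-default rate-law keys on read.
#' @return `read_kinetic_model` returns a [kinetic_model()];
#'   `write_kinetic_model` returns `path` invisibly.
#' @export
write_kinetic_model <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(model$rate_tags == "custom")) {
    stop("models with custom rate-law closures cannot be serialized; ",
         "supply them as a rate registry on read instead")
  }
  spec <- list(
    states = as.list(model$states),
    initial_conditions = as.list(model$initial_conditions),
    unknown_ics = as.list(model$unknown_ics),
    output_map = as.list(model$output_map),
    extracellular = as.list(model$extracellular),
    dilution_rate = model$dilution_rate,
    parameters = as.list(model$parameters),
    stoichiometry = lapply(model$stoichiometry, as.list),
    rate_laws = as.list(model$rate_tags)
  )
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @rdname write_kinetic_model
#' @export
read_kinetic_model <- function(path, rate_registry = list()) {
  spec <- yaml::read_yaml(path)
  laws <- lapply(spec$rate_laws, function(tag) {
    if (identical(tag, "default")) return("default")
    fn <- rate_registry[[tag]]
    if (is.null(fn)) stop("rate-law key '", tag, "' not in rate_registry")
    fn
  })
  kinetic_model(
    states = unlist(spec$states),
    initial_conditions = unlist(spec$initial_conditions),
    parameters = unlist(spec$parameters),
    rate_laws = laws,
    stoichiometry = lapply(spec$stoichiometry, unlist),
    dilution_rate = spec$dilution_rate %||% 0,
    unknown_ics = as.character(unlist(spec$unknown_ics)),
    output_map = unlist(spec$output_map),
    extracellular = as.character(unlist(spec$extracellular))
  )
}

#' Serialize an identifiability trace as JSON
#'
#' Writes the run bookkeeping — candidate partition, per-attempt iteration
#' log, objectives, and final estimates — in a stable JSON layout.
#'
#' @param trace An [run_identifiability()] trace.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "identifiability_trace"))
  out <- list(
    mode = trace$mode,
    candidates = trace$candidates,
    selected = trace$selected,
    evaluated = trace$evaluated,
    evaluation_count = trace$evaluation_count,
    initial_objective = trace$initial_objective,
    final_objective = trace$final_objective,
    parameters = as.list(trace$parameters),
    iterations = trace$iterations,
    report = selection_report(trace)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Export collinearity angles as CSV
#'
#' Writes either the flagged-pair table (columns `parameter_1`,
#' `parameter_2`, `angle`) or the full symmetric angle matrix.
#'
#' @param angles A [collinearity_angles()] result.
#' @param path File path.
#' @param what `"pairs"` (flagged pairs) or `"matrix"`.
#' @param lower,upper Critical thresholds passed to
#'   [flag_collinear_pairs()].
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(angles, path, what = c("pairs", "matrix"),
                             lower = 5, upper = 175) {
  what <- match.arg(what)
  if (what == "pairs") {
    utils::write.csv(flag_collinear_pairs(angles, lower, upper), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(angles$angles), path, quote = FALSE)
  }
  invisible(path)
}
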