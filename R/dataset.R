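#' Heteroscedastic measurement-error model
#'
#' The standard deviation of a measured value \eqn{y_i} is modelled as
#' \deqn{\sigma_{y_i} = a \, y_i + b,} a proportional component `a`
#' (dimensionless) plus an additive floor `b` (mM). Both must be
#' non-negative and not both zero, so that every record carries a strictly
#' positive weight.
#'
#' @param a Proportional coefficient (dimensionless), `>= 0`.
#' @param b Additive floor (mM), `>= 0`.
#' @return Object of class `error_model`.
#' @export
error_model <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a < 0 || b < 0 || (a == 0 && b == 0)) {
    stop("error model requires a >= 0, b >= 0, and not both zero")
  }
  structure(list(a = a, b = b), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> sigma_y = ", format(x$a), " * y + ", format(x$b),
      "\n", sep = "")
  invisible(x)
}

record_sigmas <- function(values, em) {
  s <- em$a * values + em$b
  if (any(s <= 0)) {
    stop("non-positive measurement sigma; with b = 0 every value must be > 0")
  }
  s
}

#' Bundle time-series measurements with their error model
#'
#' Measurements are held in long format — one row per (time, variable,
#' value) triple — which naturally supports partially observed and
#' asynchronous data: combinations that were never measured are simply
#' absent. Each record is assigned the weight \eqn{\sigma_{y_i} = a y_i + b}
#' evaluated on the *experimental* value, so the weighting matrix stays
#' fixed during optimization.
#'
#' @param records Data frame with columns `time` (s), `variable` (state
#'   name), `value` (mM).
#' @param error_model An [error_model()].
#' @param model Optional [kinetic_model()]; if given, record variables are
#'   checked against its measurable outputs.
#' @return Object of class `kinetic_dataset`: the records (with an appended
#'   `sigma` column) and the error model.
#' @export
kinetic_dataset <- function(records, error_model, model = NULL) {
  stopifnot(is.data.frame(records),
            all(c("time", "variable", "value") %in% names(records)))
  if (nrow(records) == 0L) stop("dataset must contain at least one record")
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("record times must be finite and non-negative")
  }
  if (any(!is.finite(records$value))) stop("record values must be finite")
  if (!inherits(error_model, "error_model")) {
    stop("error_model must be created with error_model()")
  }
  if (!is.null(model) && !all(records$variable %in% model$output_map)) {
    bad <- setdiff(unique(records$variable), model$output_map)
    stop("records for unmeasurable variables: ", paste(bad, collapse = ", "))
  }
  records <- records[order(records$time, records$variable), , drop = FALSE]
  rownames(records) <- NULL
  records$variable <- as.character(records$variable)
  records$sigma <- record_sigmas(records$value, error_model)
  structure(list(records = records, error_model = error_model),
            class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat("<kinetic_dataset> ", nrow(x$records), " records, ",
      length(unique(x$records$variable)), " variables, t in [",
      format(min(x$records$time)), ", ", format(max(x$records$time)),
      "] s\n", sep = "")
  invisible(x)
}

#' Read / write datasets as long-format CSV
#'
#' The on-disk format is a plain CSV with columns `time`, `variable`,
#' `value`; missing (time, variable) combinations are simply absent.
#'
#' @param path File path.
#' @param error_model An [error_model()] attached on read.
#' @param dataset A [kinetic_dataset()] to write.
#' @return `read_dataset_csv` returns a [kinetic_dataset()];
#'   `write_dataset_csv` returns `path` invisibly.
#' @export
read_dataset_csv <- function(path, error_model) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kinetic_dataset(df[, c("time", "variable", "value")], error_model)
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(dataset$records[, c("time", "variable", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Model predictions aligned to the dataset records: one value per record.
predict_records <- function(model, parameters, dataset, ...) {
  rec <- dataset$records
  tt <- sort(unique(rec$time))
  traj <- simulate_model(model, parameters = parameters, times = tt, ...)
  idx <- cbind(match(rec$time, tt),
               match(rec$variable, model$states) + 1L)
  unname(traj[idx])
}
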