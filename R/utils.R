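`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
new_integration_failure <- function(message, data = list()) {
  structure(
    class = c("identestim_integration_failure", "identestim_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
}

stop_integration_failure <- function(message, data = list()) {
  stop(new_integration_failure(message, data))
}

#' Test whether a condition is a typed integration failure
#'
#' Integration failures (step-size collapse, non-finite derivatives, runaway
#' negative concentrations) are signalled as conditions of class
#' `identestim_integration_failure` so that the selection procedure can treat
#' them as estimation failures rather than hard crashes.
#'
#' @param x An object, typically caught via [tryCatch()].
#' @return `TRUE` if `x` is an integration-failure condition.
#' @export
is_integration_failure <- function(x) {
  inherits(x, "identestim_integration_failure")
}

# Draw from a Gaussian truncated at zero by resampling; returns the draws and
# the number of rejected (negative) proposals.
rnorm_nonneg <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  rejected <- 0L
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    rejected <- rejected + length(bad)
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- 0
  list(values = out, rejected = rejected)
}
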