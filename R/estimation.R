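#' Weighted-least-squares objective
#'
#' The maximum-likelihood objective under independent Gaussian errors with a
#' diagonal covariance:
#' \deqn{S(\theta) = \sum_i \frac{(y_i^C - y_i^E)^2}{\sigma_{y_i}^2},}
#' where \eqn{y^C} are model predictions at the dataset's (time, variable)
#' records, \eqn{y^E} the measured values, and \eqn{\sigma_{y_i} = a y_i^E +
#' b} is evaluated on the *experimental* values so the quadratic form is
#' fixed during optimization.
#'
#' @param model A [kinetic_model()].
#' @param parameters Full candidate vector (kinetic parameters plus
#'   `ic_<state>` pseudo-parameters).
#' @param dataset A [kinetic_dataset()].
#' @return Scalar objective value (non-negative; zero iff a perfect fit).
#'   Integration failures propagate as typed conditions.
#' @export
wls_objective <- function(model, parameters, dataset) {
  r <- wls_residuals(model, parameters, dataset)
  sum(r^2)
}

wls_residuals <- function(model, parameters, dataset) {
  yc <- predict_records(model, parameters, dataset)
  r <- (yc - dataset$records$value) / dataset$records$sigma
  if (!all(is.finite(r))) stop_integration_failure("non-finite residuals")
  r
}

#' Fisher information matrix, covariance, and normalized uncertainties
#'
#' From the raw sensitivity columns \eqn{B} of the estimated subset and the
#' per-record standard deviations, computes
#' \deqn{FIM = B^T V_Y^{-1} B, \qquad V_\Theta = FIM^{-1},}
#' with \eqn{V_Y = diag(\sigma_{y_i}^2)}, and reports the normalized
#' standard deviation \eqn{\sigma_{\theta_j}/\theta_j =
#' \sqrt{(V_\Theta)_{jj}}/|\theta_j|} for each parameter. The diagonal of
#' \eqn{V_\Theta} carries the parameter variabilities; its off-diagonal
#' terms carry the parameter interactions and are preserved in the returned
#' covariance.
#'
#' Singularity is judged in a scale-invariant way: the reciprocal condition
#' number (eigenvalue ratio) of the parameter-scaled matrix
#' \eqn{D \cdot FIM \cdot D}, \eqn{D = diag(\theta)}, must exceed
#' `rcond_tol`, otherwise no inversion is attempted and the singular signal
#' is returned.
#'
#' @param B Numeric matrix of raw sensitivities (records x subset
#'   parameters) evaluated at the estimate.
#' @param sigmas Per-record standard deviations (same row order as `B`).
#' @param theta Named estimate vector for the subset (column order of `B`).
#' @param rcond_tol Reciprocal-condition threshold for the singular signal.
#' @return List with `fim`, `covariance` (`NULL` when singular),
#'   `normalized_std`, `rcond`, and logical `singular`.
#' @export
compute_fim <- function(B, sigmas, theta, rcond_tol = 1e-10) {
  stopifnot(is.matrix(B), nrow(B) == length(sigmas),
            ncol(B) == length(theta))
  W <- 1 / sigmas^2
  fim <- crossprod(B * sqrt(W))
  fim <- (fim + t(fim)) / 2
  dimnames(fim) <- list(names(theta), names(theta))
  scaled <- fim * outer(abs(theta), abs(theta))
  ev <- eigen(scaled, symmetric = TRUE, only.values = TRUE)$values
  rc <- if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
  if (!is.finite(rc) || rc < rcond_tol || min(ev) < -rcond_tol * max(abs(ev))) {
    return(list(fim = fim, covariance = NULL,
                normalized_std = rep(NA_real_, length(theta)),
                rcond = rc, singular = TRUE))
  }
  # invert through the well-conditioned scaled form:
  # V = D (D FIM D)^{-1} D with D = diag(|theta|)
  d <- abs(theta)
  V <- solve(scaled) * outer(d, d)
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fim)
  nstd <- sqrt(pmax(diag(V), 0)) / abs(theta)
  list(fim = fim, covariance = V,
       normalized_std = stats::setNames(nstd, names(theta)),
       rcond = rc, singular = FALSE)
}

#' Control settings for subset estimation
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations per call.
#' @param ftol,xtol Convergence tolerances on the objective and the step.
#' @param rcond_tol Reciprocal-condition threshold for the singular-FIM
#'   failure signal.
#' @param max_nstd Cap on the normalized standard deviation
#'   \eqn{\sigma_\theta/\theta} of any estimated parameter. The default
#'   0.5 is the two-sided 95 percent significance rule (\eqn{\theta /
#'   \sigma_\theta \ge 2}): an optimum whose relative uncertainty
#'   exceeds it is statistically indistinguishable from no information, so
#'   the attempt is treated as a failed estimation and the parameter is
#'   demoted and retried after the selected values have moved.
#' @param log_transform Estimate positive parameters on the log scale
#'   (enforces positivity of rate constants and concentrations); parameters
#'   entering at non-positive values are optimized untransformed.
#' @param span Box half-width around the entry value, in orders of
#'   magnitude, within which each log-transformed parameter may move (a
#'   loose guard keeping the search out of integrator-breaking regions;
#'   untransformed parameters are unbounded).
#' @param step_rel Relative finite-difference step for the post-fit
#'   sensitivity evaluation.
#' @return List of settings for [estimate_subset()].
#' @export
estimation_control <- function(max_iter = 200, ftol = 1e-8, xtol = 1e-8,
                               rcond_tol = 1e-10, max_nstd = 0.5,
                               log_transform = TRUE, span = 6,
                               step_rel = 1e-6) {
  list(max_iter = max_iter, ftol = ftol, xtol = xtol,
       rcond_tol = rcond_tol, max_nstd = max_nstd,
       log_transform = log_transform, span = span, step_rel = step_rel)
}

#' Estimate a parameter subset by weighted least squares
#'
#' Minimizes [wls_objective()] over the designated subset with every other
#' parameter frozen at its current value, using Levenberg-Marquardt least
#' squares on the weighted residuals. Initial values are taken from the
#' supplied full vector, which carries any previous re-estimates.
#'
#' The call *fails* (with `success = FALSE` and a reason) when any of the
#' following occurs: the optimizer does not converge
#' (`"optimizer_nonconvergence"`); an integration failure interrupts an
#' objective evaluation (`"integration_failure"`); the Fisher information
#' matrix at the optimum is numerically singular (`"singular_fim"`); the
#' fitted value of a log-transformed parameter is pinned at the edge of its
#' search box, i.e. the apparent optimum is not interior (`"bound_hit"`);
#' the normalized standard deviation of any estimate exceeds
#' `control$max_nstd` (`"information_deficient"`); or the final objective
#' exceeds its entry value
#' (`"objective_nonimprovement"`). On failure the returned parameter vector
#' is the unchanged entry vector, so callers can rely on rollback semantics.
#'
#' @param model A [kinetic_model()].
#' @param parameters Full candidate vector (entry values).
#' @param subset Character vector of candidate names to estimate.
#' @param dataset A [kinetic_dataset()].
#' @param control An [estimation_control()] list.
#' @return Object of class `estimation_result`: `success`,
#'   `failure_reason`, `estimated_values`, `parameters` (updated full
#'   vector on success, rolled back on failure), `objective`,
#'   `objective_entry`, `fim`, `covariance`, `normalized_std`, `subset`,
#'   `info` (optimizer diagnostics).
#' @export
estimate_subset <- function(model, parameters, subset, dataset,
                            control = estimation_control()) {
  stopifnot(length(subset) > 0L, all(subset %in% names(parameters)))
  entry <- parameters

  fail <- function(reason, extra = list()) {
    structure(c(list(success = FALSE, failure_reason = reason,
                     estimated_values = NULL, parameters = entry,
                     objective = NA_real_, objective_entry = s_entry,
                     fim = NULL, covariance = NULL, normalized_std = NULL,
                     subset = subset), extra),
              class = "estimation_result")
  }

  s_entry <- tryCatch(wls_objective(model, entry, dataset),
                      identestim_integration_failure = function(e) NA_real_)
  if (!is.finite(s_entry)) {
    return(fail("integration_failure"))
  }

  use_log <- control$log_transform & entry[subset] > 0
  to_opt <- function(x) ifelse(use_log, log(x), x)
  from_opt <- function(x) ifelse(use_log, exp(x), x)

  had_integration_failure <- FALSE
  resid_fn <- function(par) {
    pp <- entry
    pp[subset] <- from_opt(par)
    tryCatch(wls_residuals(model, pp, dataset),
             identestim_integration_failure = function(e) {
               had_integration_failure <<- TRUE
               rep(1e6, nrow(dataset$records))
             })
  }

  par0 <- to_opt(unname(entry[subset]))
  halfwidth <- (control$span %||% 6) * log(10)
  lower <- ifelse(use_log, par0 - halfwidth, -Inf)
  upper <- ifelse(use_log, par0 + halfwidth, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = control$max_iter, ftol = control$ftol,
        ptol = control$xtol, maxfev = 100 * (length(subset) + 1))),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer_nonconvergence"))
  if (had_integration_failure) return(fail("integration_failure"))
  # MINPACK info 1-3: ftol/ptol satisfied; 4: gradient criterion (gtol)
  if (!fit$info %in% 1:4) {
    return(fail("optimizer_nonconvergence", list(info = fit$info)))
  }

  # a solution pinned at the search-box edge is not an interior optimum
  at_edge <- is.finite(lower) & (fit$par <= lower + 1e-8 * halfwidth |
                                 fit$par >= upper - 1e-8 * halfwidth)
  if (any(at_edge)) {
    return(fail("bound_hit", list(at_bound = subset[at_edge])))
  }
  est <- stats::setNames(from_opt(fit$par), subset)
  pp <- entry
  pp[subset] <- est
  s_final <- tryCatch(wls_objective(model, pp, dataset),
                      identestim_integration_failure = function(e) NA_real_)
  if (!is.finite(s_final)) return(fail("integration_failure"))
  if (s_final > s_entry * (1 + 1e-12) && s_final > s_entry + 1e-12) {
    return(fail("objective_nonimprovement", list(objective_final = s_final)))
  }

  sens <- tryCatch(
    compute_sensitivities(model, pp, dataset, which = subset,
                          step_rel = control$step_rel),
    identestim_integration_failure = function(e) NULL)
  if (is.null(sens)) return(fail("integration_failure"))
  fi <- compute_fim(sens$raw, dataset$records$sigma, pp[subset],
                    rcond_tol = control$rcond_tol)
  if (fi$singular) {
    return(fail("singular_fim", list(rcond = fi$rcond)))
  }
  max_nstd <- control$max_nstd %||% Inf
  if (any(fi$normalized_std > max_nstd)) {
    return(fail("information_deficient",
                list(normalized_std = fi$normalized_std)))
  }

  structure(list(success = TRUE, failure_reason = NULL,
                 estimated_values = est, parameters = pp,
                 objective = s_final, objective_entry = s_entry,
                 fim = fi$fim, covariance = fi$covariance,
                 normalized_std = fi$normalized_std, subset = subset,
                 info = fit$info),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result> ", if (x$success) "success" else
    paste0("FAILED (", x$failure_reason, ")"),
    "; subset of ", length(x$subset), "\n", sep = "")
  if (x$success) {
    cat("  objective: ", format(x$objective_entry), " -> ",
        format(x$objective), "\n", sep = "")
    df <- data.frame(estimate = x$estimated_values,
                     normalized_std = x$normalized_std)
    print(utils::head(df, 12))
  }
  invisible(x)
}

#' Tabulate an estimation result in reporting format
#'
#' Produces the standard reporting layout for identifiable parameters:
#' initial estimate, estimated value, and normalized standard deviation
#' \eqn{\sigma_\theta/\theta}.
#'
#' @param result An [estimate_subset()] result (successful).
#' @param initial Named vector of the initial estimates to report against.
#' @return Data frame with columns `parameter`, `initial_estimate`,
#'   `estimated_value`, `normalized_std`.
#' @export
estimation_report <- function(result, initial) {
  stopifnot(inherits(result, "estimation_result"), isTRUE(result$success))
  data.frame(parameter = result$subset,
             initial_estimate = unname(initial[result$subset]),
             estimated_value = unname(result$estimated_values),
             normalized_std = unname(result$normalized_std),
             stringsAsFactors = FALSE)
}
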