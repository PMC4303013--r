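#' Local sensitivity matrix of model outputs with respect to parameters
#'
#' Computes the local sensitivity matrix \eqn{B} with entries
#' \eqn{\partial y_i / \partial \theta_j}, stacked over all observed
#' (time, variable) records (rows) and candidate parameters (columns), by
#' finite differences around the supplied evaluation point. The normalized
#' form \eqn{B_N} rescales each entry by \eqn{\theta_j / y_i} so that
#' parameters and outputs of different magnitudes become comparable; rows
#' where the predicted output is smaller than `eps_y` in magnitude are
#' normalized by `eps_y` instead, guarding against division by near-zero
#' observations.
#'
#' Unknown-initial-condition pseudo-parameters (`ic_<state>`) get sensitivity
#' columns exactly like kinetic parameters. An integration failure at any
#' perturbed point is propagated as a typed failure (the parameter is
#' unevaluable at this point).
#'
#' @param model A [kinetic_model()].
#' @param parameters Named full candidate vector (evaluation point); defaults
#'   to the model's declared estimates (unknown ICs must then be present in
#'   the model's initial conditions).
#' @param dataset A [kinetic_dataset()].
#' @param scheme `"forward"` (one extra simulation per parameter) or
#'   `"central"` (two, with O(h^2) error).
#' @param which Candidate names to differentiate; defaults to all candidates.
#' @param step_rel Relative perturbation; the step is
#'   `step_rel * max(abs(theta_j), theta_floor)`.
#' @param theta_floor Absolute floor protecting near-zero parameters.
#' @param eps_y Output-magnitude guard used in the normalization.
#' @return Object of class `sensitivity_matrix` with fields `raw`,
#'   `normalized` (records x parameters matrices), `records`, `predicted`,
#'   `parameters` (the evaluation point), `scheme`.
#' @export
compute_sensitivities <- function(model, parameters = NULL, dataset,
                                  scheme = c("forward", "central"),
                                  which = NULL, step_rel = 1e-6,
                                  theta_floor = 1e-8, eps_y = 1e-12) {
  scheme <- match.arg(scheme)
  if (is.null(parameters)) parameters <- model$parameters
  cand <- which %||% intersect(candidate_names(model), names(parameters))
  if (!all(cand %in% names(parameters))) {
    stop("parameters vector is missing candidates: ",
         paste(setdiff(cand, names(parameters)), collapse = ", "))
  }
  y0 <- predict_records(model, parameters, dataset)
  n <- length(y0)
  raw <- matrix(0, n, length(cand), dimnames = list(NULL, cand))
  for (j in seq_along(cand)) {
    th <- parameters[[cand[j]]]
    h <- step_rel * max(abs(th), theta_floor)
    pp <- parameters
    pp[[cand[j]]] <- th + h
    yp <- predict_records(model, pp, dataset)
    if (scheme == "forward") {
      raw[, j] <- (yp - y0) / h
    } else {
      pm <- parameters
      pm[[cand[j]]] <- th - h
      ym <- predict_records(model, pm, dataset)
      raw[, j] <- (yp - ym) / (2 * h)
    }
  }
  denom <- pmax(abs(y0), eps_y)
  theta <- unname(parameters[cand])
  normalized <- sweep(raw, 1, denom, "/")
  normalized <- sweep(normalized, 2, theta, "*")
  structure(list(raw = raw, normalized = normalized,
                 records = dataset$records, predicted = y0,
                 parameters = parameters, scheme = scheme,
                 step_rel = step_rel),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("<sensitivity_matrix> ", nrow(x$raw), " records x ", ncol(x$raw),
      " parameters (", x$scheme, " differences)\n", sep = "")
  invisible(x)
}

sensitivity_columns <- function(S, normalized = TRUE) {
  if (inherits(S, "sensitivity_matrix")) {
    if (normalized) S$normalized else S$raw
  } else if (is.matrix(S)) {
    S
  } else {
    stop("expected a sensitivity_matrix or a plain matrix of columns")
  }
}

#' Collinearity angles between sensitivity vectors
#'
#' For every pair of sensitivity columns \eqn{b_{\theta_i}, b_{\theta_j}}
#' the angle
#' \deqn{\angle_{i,j} = \arccos \frac{b_{\theta_i}^T b_{\theta_j}}
#'       {\|b_{\theta_i}\| \|b_{\theta_j}\|} \in [0, \pi]}
#' is reported in degrees. Values near 90 deg indicate linear independence;
#' values near 0 or 180 deg flag parameter pairs that the data cannot tell
#' apart (a screen over pairs only — higher-order collinearity is handled by
#' the Gram-Schmidt ranking). Zero-norm columns yield `NA` angles and are
#' listed as degenerate rather than silently included.
#'
#' @param S A `sensitivity_matrix` (normalized columns are used) or a plain
#'   matrix whose columns are sensitivity vectors.
#' @param normalized Use the normalized matrix when `S` is a
#'   `sensitivity_matrix`.
#' @return Object of class `collinearity_angles`: a symmetric matrix of
#'   angles in degrees (diagonal 0) plus the names of degenerate columns.
#' @export
collinearity_angles <- function(S, normalized = TRUE) {
  B <- sensitivity_columns(S, normalized)
  if (ncol(B) < 2L) stop("need at least 2 sensitivity columns")
  nrm <- sqrt(colSums(B^2))
  degenerate <- colnames(B)[nrm == 0]
  G <- crossprod(B)
  denom <- outer(nrm, nrm)
  cosv <- G / denom
  cosv[!is.finite(cosv)] <- NA_real_
  cosv <- pmin(pmax(cosv, -1), 1)
  ang <- acos(cosv) * 180 / pi
  diag(ang) <- ifelse(nrm > 0, 0, NA_real_)
  structure(list(angles = ang, degenerate = degenerate),
            class = "collinearity_angles")
}

#' @export
print.collinearity_angles <- function(x, ...) {
  np <- ncol(x$angles)
  cat("<collinearity_angles> ", np, " parameters, ",
      np * (np - 1) / 2, " pairs", sep = "")
  if (length(x$degenerate)) {
    cat("; degenerate columns: ", paste(x$degenerate, collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Flag parameter pairs with critical collinearity angles
#'
#' Lists pairs whose angle falls below `lower` or above `upper` degrees —
#' the near-parallel and near-antiparallel pairs expected to resist joint
#' estimation until one member has been re-estimated.
#'
#' @param angles A [collinearity_angles()] result.
#' @param lower,upper Critical thresholds in degrees.
#' @return Data frame with columns `parameter_1`, `parameter_2`, `angle`,
#'   ordered by extremity.
#' @export
flag_collinear_pairs <- function(angles, lower = 5, upper = 175) {
  A <- angles$angles
  nm <- colnames(A)
  idx <- which(upper.tri(A) & (A < lower | A > upper), arr.ind = TRUE)
  out <- data.frame(parameter_1 = nm[idx[, 1]],
                    parameter_2 = nm[idx[, 2]],
                    angle = A[idx],
                    stringsAsFactors = FALSE)
  out[order(pmin(out$angle, 180 - out$angle)), , drop = FALSE]
}
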