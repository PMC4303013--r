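#' Rank candidate parameters by estimability
#'
#' Orders the candidate parameters from most to least estimable. The most
#' estimable parameter is the one whose sensitivity column has the largest
#' Euclidean norm; to discount linear dependence with parameters that have
#' already been selected, every candidate column is first orthogonalized
#' against the span of the selected columns (modified Gram-Schmidt, which is
#' the numerically stable formulation of the classical procedure) and the
#' *residual* norm is ranked. With an empty selected set the ranking reduces
#' to plain descending column norms. Ranking operates on the normalized
#' sensitivity matrix by default, so magnitudes of different outputs and
#' parameters do not distort the ordering.
#'
#' Ties are broken by column declaration order, which makes runs
#' reproducible. Selected columns that are (numerically) linearly dependent
#' among themselves are skipped as pivots, with a warning.
#'
#' @param S A `sensitivity_matrix` or a plain matrix whose columns are
#'   sensitivity vectors.
#' @param selected Character vector of already-selected parameter names
#'   (columns of `S`), in selection order.
#' @param candidates Character vector of parameters to rank; defaults to all
#'   non-selected columns.
#' @param normalized Use the normalized matrix when `S` is a
#'   `sensitivity_matrix`.
#' @param pivot_tol Relative tolerance below which a selected column is
#'   treated as linearly dependent and dropped from the basis.
#' @return Object of class `estimability_ranking`: a data frame with
#'   columns `parameter` and `residual_norm`, ordered most to least
#'   estimable, with the selected set as an attribute.
#' @export
rank_parameters <- function(S, selected = character(), candidates = NULL,
                            normalized = TRUE, pivot_tol = 1e-12) {
  B <- sensitivity_columns(S, normalized)
  if (is.null(colnames(B))) stop("sensitivity columns must be named")
  candidates <- candidates %||% setdiff(colnames(B), selected)
  if (!all(candidates %in% colnames(B))) {
    stop("candidates missing from the sensitivity matrix: ",
         paste(setdiff(candidates, colnames(B)), collapse = ", "))
  }
  if (!all(selected %in% colnames(B))) {
    stop("selected parameters missing from the sensitivity matrix: ",
         paste(setdiff(selected, colnames(B)), collapse = ", "))
  }

  Q <- orthonormal_basis(B[, selected, drop = FALSE], pivot_tol)
  C <- B[, candidates, drop = FALSE]
  if (ncol(Q)) {
    C <- C - Q %*% crossprod(Q, C)  # residual after projection onto span
  }
  norms <- sqrt(colSums(C^2))
  # descending residual norm; ties broken by declaration order in B
  decl <- match(candidates, colnames(B))
  ord <- order(-norms, decl)
  out <- data.frame(parameter = candidates[ord],
                    residual_norm = unname(norms[ord]),
                    stringsAsFactors = FALSE)
  structure(out, selected = selected, class = c("estimability_ranking",
                                                "data.frame"))
}

# Modified Gram-Schmidt orthonormal basis of the columns of M, skipping
# near-zero pivots (relative to the largest column norm).
orthonormal_basis <- function(M, pivot_tol = 1e-12) {
  if (ncol(M) == 0L) return(matrix(0, nrow(M), 0))
  scale <- max(sqrt(colSums(M^2)))
  if (scale == 0) return(matrix(0, nrow(M), 0))
  Q <- matrix(0, nrow(M), 0)
  dropped <- character(0)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    for (k in seq_len(ncol(Q))) v <- v - drop(crossprod(Q[, k], v)) * Q[, k]
    nv <- sqrt(sum(v^2))
    if (nv <= pivot_tol * scale) {
      dropped <- c(dropped, colnames(M)[j] %||% as.character(j))
    } else {
      Q <- cbind(Q, v / nv)
    }
  }
  if (length(dropped)) {
    warning("linearly dependent selected columns skipped during ",
            "orthogonalization: ", paste(dropped, collapse = ", "))
  }
  Q
}

#' @export
print.estimability_ranking <- function(x, ...) {
  sel <- attr(x, "selected")
  cat("<estimability_ranking> ", nrow(x), " candidates",
      if (length(sel)) paste0(" (orthogonalized against ", length(sel),
                              " selected)") else "", "\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}
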