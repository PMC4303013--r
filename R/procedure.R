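#' Control settings for the identifiability procedure
#'
#' @param estimation An [estimation_control()] list passed to every subset
#'   estimation.
#' @param sensitivity_scheme Finite-difference scheme for the ranking
#'   sensitivities.
#' @param normalized Rank on the normalized sensitivity matrix (the
#'   default); set `FALSE` to rank on raw sensitivities.
#' @param max_seconds Optional wall-clock budget; the run stops cleanly (and
#'   is flagged) once exceeded. `Inf` disables the budget.
#' @return List of settings for [run_identifiability()].
#' @export
identifiability_control <- function(estimation = estimation_control(),
                                    sensitivity_scheme = "forward",
                                    normalized = TRUE,
                                    max_seconds = Inf) {
  list(estimation = estimation, sensitivity_scheme = sensitivity_scheme,
       normalized = normalized, max_seconds = max_seconds)
}

#' Intensive parameter identifiability with simultaneous estimation
#'
#' Runs the one-by-one selection procedure over three bookkeeping sets: the
#' selected parameters \eqn{\Theta^{(S)}}, the non-selected parameters
#' \eqn{\Theta^{(NS)}}, and the evaluated parameters \eqn{\Theta^{(E)}}
#' (those that failed at the current configuration of the selected set).
#'
#' The loop: (1) all candidates start in \eqn{\Theta^{(NS)}}; (2)
#' sensitivities are recomputed at the *current* parameter vector and
#' \eqn{\Theta^{(NS)}} is ranked by residual norm after Gram-Schmidt
#' orthogonalization against the selected columns; (3) the top-ranked
#' candidate joins \eqn{\Theta^{(S)}} and the whole selected set is
#' re-estimated; (4a) on success the vector is updated, *all* of
#' \eqn{\Theta^{(E)}} returns to \eqn{\Theta^{(NS)}} for re-evaluation
#' (their estimability may have changed now that the selected values moved),
#' and the loop re-ranks; (4b) on failure the candidate is rolled back and
#' demoted to \eqn{\Theta^{(E)}}, and the *next* entry of the existing rank
#' is tried without re-ranking (the evaluation point has not changed); (5)
#' the run stops when \eqn{\Theta^{(NS)}} is empty. Every candidate ends in
#' \eqn{\Theta^{(S)}} or \eqn{\Theta^{(E)}}, and the total number of
#' estimation attempts is at most \eqn{nP(nP+1)/2}.
#'
#' In `"first_failure"` mode the run instead stops at the first failed
#' inclusion — the classical behaviour of ranking-based selection — which
#' [compare_baseline()] uses as the reference.
#'
#' Unknown initial conditions are bootstrapped via
#' [bootstrap_unknown_ics()] before the first iteration and enter the
#' candidate set as pseudo-parameters.
#'
#' A custom `estimator` (signature `function(model, parameters, subset,
#' dataset, control, context)`, returning an object with at least
#' `success`, `parameters`, `objective`) can replace the weighted
#' least-squares estimator; deterministic mock estimators built from
#' [make_worst_case_oracle()] allow dry runs that exercise only the
#' selection accounting, in which case `model` and `dataset` may be `NULL`
#' and candidates are ranked in declaration order.
#'
#' @param model A [kinetic_model()], or `NULL` for oracle-driven dry runs.
#' @param dataset A [kinetic_dataset()], or `NULL` for dry runs.
#' @param candidates Character vector of candidate names; defaults to
#'   [candidate_names()] of the model.
#' @param mode `"intensive"` (evaluate every parameter, recycling failures
#'   after each success) or `"first_failure"` (stop at the first failure).
#' @param estimator Optional estimator override (see Details).
#' @param control An [identifiability_control()] list.
#' @param initial_parameters Optional named vector overriding the model's
#'   initial estimates.
#' @return Object of class `identifiability_trace`; see
#'   [print.identifiability_trace()] and [selection_report()].
#' @examples
#' # worst-case accounting dry run: 3 candidates, 6 attempts
#' tr <- run_identifiability(NULL, NULL, candidates = c("a", "b", "c"),
#'                           estimator = oracle_estimator(make_worst_case_oracle(3)))
#' tr$evaluation_count
#' @export
run_identifiability <- function(model, dataset, candidates = NULL,
                                mode = c("intensive", "first_failure"),
                                estimator = NULL,
                                control = identifiability_control(),
                                initial_parameters = NULL) {
  mode <- match.arg(mode)
  mock <- is.null(model)
  if (mock && is.null(estimator)) {
    stop("dry runs without a model require an explicit estimator")
  }
  if (is.null(candidates)) {
    if (mock) stop("candidates must be given for dry runs")
    candidates <- candidate_names(model)
  }
  stopifnot(length(candidates) > 0L, !anyDuplicated(candidates))

  if (mock) {
    params <- stats::setNames(rep(1, length(candidates)), candidates)
  } else {
    params <- model$parameters
    if (!is.null(initial_parameters)) {
      params[names(initial_parameters)] <- initial_parameters
    }
    if (length(model$unknown_ics)) {
      boot <- bootstrap_unknown_ics(model, parameters = params,
                                    dataset = dataset)
      ic_nm <- names(boot)
      keep <- !(ic_nm %in% names(initial_parameters %||% character()))
      params[ic_nm[keep]] <- boot[keep]
      params[ic_nm[!keep]] <- initial_parameters[ic_nm[!keep]]
    }
    missing <- setdiff(candidates, names(params))
    if (length(missing)) {
      stop("candidates without values: ", paste(missing, collapse = ", "))
    }
  }
  if (is.null(estimator)) {
    estimator <- function(model, parameters, subset, dataset, control,
                          context) {
      estimate_subset(model, parameters, subset, dataset,
                      control = control$estimation)
    }
  }

  obj <- NA_real_
  if (!mock) {
    obj <- tryCatch(wls_objective(model, params, dataset),
                    identestim_integration_failure = function(e) NA_real_)
    if (!is.finite(obj)) {
      stop("model is not simulable at the initial parameter vector; ",
           "revise the initial estimates before running the procedure")
    }
  }
  initial_objective <- obj
  initial_params <- params

  sel <- character(0)
  ev <- character(0)
  ns <- candidates
  rows <- vector("list", 0L)
  eval_count <- 0L
  round_i <- 0L
  final_result <- NULL
  budget_exceeded <- FALSE
  t0 <- Sys.time()

  check_partition <- function() {
    all_sets <- c(sel, ns, ev)
    stopifnot(!anyDuplicated(all_sets),
              setequal(all_sets, candidates))
  }

  repeat {
    if (length(ns) == 0L) break
    if (as.numeric(Sys.time() - t0, units = "secs") > control$max_seconds) {
      budget_exceeded <- TRUE
      break
    }
    round_i <- round_i + 1L
    if (mock) {
      # dry runs carry no sensitivity information: rank by declaration order
      rank_df <- data.frame(parameter = candidates[candidates %in% ns],
                            residual_norm = NA_real_,
                            stringsAsFactors = FALSE)
    } else {
      sens <- compute_sensitivities(
        model, params, dataset, scheme = control$sensitivity_scheme,
        which = candidates)
      rank_df <- rank_parameters(sens, selected = sel, candidates = ns,
                                 normalized = control$normalized)
    }
    round_size <- length(ns)
    round_success <- FALSE
    attempt <- 0L
    for (k in seq_len(nrow(rank_df))) {
      cand <- rank_df$parameter[k]
      attempt <- attempt + 1L
      eval_count <- eval_count + 1L
      res <- estimator(model, params, c(sel, cand), dataset, control,
                       context = list(candidate = cand, selected = sel,
                                      round = round_i, attempt = attempt,
                                      round_size = round_size,
                                      objective = obj))
      ok <- isTRUE(res$success)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = eval_count, round = round_i, candidate = cand,
        rank_position = k, residual_norm = rank_df$residual_norm[k],
        outcome = if (ok) "success" else "failure",
        reason = if (ok) NA_character_ else
          (res$failure_reason %||% "failure"),
        objective_before = obj,
        objective_after = if (ok) (res$objective %||% obj) else obj,
        n_selected = length(sel) + as.integer(ok),
        stringsAsFactors = FALSE)
      if (ok) {
        sel <- c(sel, cand)
        ns <- setdiff(ns, cand)
        if (!is.null(res$parameters)) params <- res$parameters
        if (!is.null(res$objective) && is.finite(res$objective)) {
          obj <- res$objective
        }
        final_result <- res
        # recycle every evaluated parameter for re-evaluation
        ns <- c(ns, ev)
        ev <- character(0)
        round_success <- TRUE
        check_partition()
        break
      } else {
        ns <- setdiff(ns, cand)
        ev <- c(ev, cand)
        check_partition()
        if (mode == "first_failure") break
      }
    }
    if (mode == "first_failure" && !round_success) break
    if (!round_success) break  # every remaining candidate failed
  }

  iterations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iteration = integer(0), round = integer(0),
               candidate = character(0), rank_position = integer(0),
               residual_norm = numeric(0), outcome = character(0),
               reason = character(0), objective_before = numeric(0),
               objective_after = numeric(0), n_selected = integer(0))

  structure(list(
    mode = mode,
    candidates = candidates,
    selected = sel,
    evaluated = ev,
    nonselected = ns,
    parameters = params,
    initial_parameters = initial_params,
    initial_objective = initial_objective,
    final_objective = obj,
    evaluation_count = eval_count,
    iterations = iterations,
    final_result = final_result,
    budget_exceeded = budget_exceeded
  ), class = "identifiability_trace")
}

#' @export
print.identifiability_trace <- function(x, ...) {
  cat("<identifiability_trace> mode = ", x$mode, "\n", sep = "")
  cat("  candidates: ", length(x$candidates),
      "; selected: ", length(x$selected),
      "; failed (evaluated): ", length(x$evaluated), "\n", sep = "")
  cat("  estimation attempts: ", x$evaluation_count,
      " (worst-case bound ", length(x$candidates) *
        (length(x$candidates) + 1) / 2, ")\n", sep = "")
  if (is.finite(x$initial_objective)) {
    cat("  objective: ", format(x$initial_objective), " -> ",
        format(x$final_objective), "\n", sep = "")
  }
  if (x$budget_exceeded) cat("  NOTE: wall-clock budget exceeded\n")
  invisible(x)
}

#' Final report of an identifiability run
#'
#' One row per selected parameter in the standard reporting layout (initial
#' estimate, estimated value, normalized standard deviation), with the
#' normalized standard deviations taken from the final successful
#' estimation of the full selected set.
#'
#' @param trace An [run_identifiability()] trace.
#' @return Data frame with columns `parameter`, `initial_estimate`,
#'   `estimated_value`, `normalized_std`.
#' @export
selection_report <- function(trace) {
  stopifnot(inherits(trace, "identifiability_trace"))
  sel <- trace$selected
  nstd <- rep(NA_real_, length(sel))
  fr <- trace$final_result
  if (!is.null(fr) && !is.null(fr$normalized_std)) {
    nstd <- unname(fr$normalized_std[match(sel, fr$subset)])
  }
  data.frame(parameter = sel,
             initial_estimate = unname(trace$initial_parameters[sel]),
             estimated_value = unname(trace$parameters[sel]),
             normalized_std = nstd,
             stringsAsFactors = FALSE)
}

#' Compare the intensive run against the classical first-failure baseline
#'
#' Reruns the procedure from the same starting point in `"first_failure"`
#' mode — selection stops as soon as one candidate fails to be included —
#' and reports both selected-set sizes and final objectives. Because the
#' intensive mode keeps evaluating (and recycling) candidates after
#' failures, its selected set is at least as large and its final objective
#' no worse.
#'
#' @param trace A completed intensive-mode trace.
#' @param model,dataset,candidates,estimator,control,initial_parameters As
#'   in [run_identifiability()]; defaults are taken from the trace where
#'   possible.
#' @return List with both traces, the selected-set sizes, the final
#'   objectives, and their ratio (intensive / first-failure).
#' @export
compare_baseline <- function(trace, model, dataset,
                             candidates = trace$candidates,
                             estimator = NULL,
                             control = identifiability_control(),
                             initial_parameters = NULL) {
  stopifnot(inherits(trace, "identifiability_trace"))
  baseline <- run_identifiability(model, dataset, candidates = candidates,
                                  mode = "first_failure",
                                  estimator = estimator, control = control,
                                  initial_parameters = initial_parameters)
  ratio <- trace$final_objective / baseline$final_objective
  list(intensive = trace, first_failure = baseline,
       n_selected_intensive = length(trace$selected),
       n_selected_first_failure = length(baseline$selected),
       objective_intensive = trace$final_objective,
       objective_first_failure = baseline$final_objective,
       objective_ratio = ratio)
}
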