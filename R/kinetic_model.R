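#' Construct a kinetic model of an ODE reaction network
#'
#' A `kinetic_model` bundles everything needed to simulate a metabolic (or
#' generic enzymatic) network: state names, initial conditions (some of which
#' may be flagged unknown), kinetic parameters with their current estimates,
#' named rate laws, a signed stoichiometric map from rates to state
#' derivatives, an optional dilution term \eqn{-\mu C} applied to
#' intracellular states, and an optional forcing function for external feeds.
#'
#' Each rate law is either a function `f(conc, params, t)` returning a scalar
#' rate in mM/s, or the string `"default"`, in which case a generic
#' Michaelis-Menten form is generated from the stoichiometry: the rate's
#' substrates are the states it consumes, and the rate becomes
#' \deqn{r = r^{max} \prod_s \frac{C_s}{K_s + C_s}}
#' with parameters named `rmax_<rate>` and `K_<rate>_<substrate>` (a
#' zero-order constant rate `rmax_<rate>` when the rate consumes no modelled
#' state). Units throughout are mM for concentrations and seconds for time.
#'
#' @param states Character vector of state (metabolite) names.
#' @param initial_conditions Named numeric vector of initial concentrations
#'   (mM), one per state.
#' @param parameters Named numeric vector of kinetic parameters (initial
#'   estimates).
#' @param rate_laws Named list of rate functions or the string `"default"`
#'   per rate; names must match the stoichiometry.
#' @param stoichiometry Named list: for each rate, a named numeric vector of
#'   signed coefficients on the states it produces (+) or consumes (-).
#' @param dilution_rate Specific growth rate \eqn{\mu} (1/s) applied as
#'   \eqn{-\mu C} to every state not listed in `extracellular`.
#' @param forcing Optional function `f(t, conc, params)` returning a named
#'   numeric vector of additive derivative contributions (e.g. feed terms).
#' @param unknown_ics Character vector of states whose initial conditions are
#'   unknown and must be estimated (as pseudo-parameters `ic_<state>`).
#' @param output_map Character vector of measurable states; defaults to all.
#' @param extracellular States exempt from the dilution term.
#' @return An object of class `kinetic_model`.
#' @seealso [simulate_model()], [bootstrap_unknown_ics()],
#'   [build_ecoli_skeleton()], [make_chain_pathway()]
#' @export
kinetic_model <- function(states, initial_conditions, parameters, rate_laws,
                          stoichiometry, dilution_rate = 0, forcing = NULL,
                          unknown_ics = character(), output_map = states,
                          extracellular = character()) {
  stopifnot(is.character(states), length(states) > 0L)
  if (anyDuplicated(states)) stop("duplicate state names")
  if (!all(names(initial_conditions) %in% states) ||
      length(initial_conditions) != length(states)) {
    stop("initial_conditions must be a named vector covering every state")
  }
  initial_conditions <- initial_conditions[states]
  if (anyDuplicated(names(parameters))) {
    stop("each parameter must be declared exactly once")
  }
  if (!all(names(stoichiometry) %in% names(rate_laws))) {
    missing <- setdiff(names(stoichiometry), names(rate_laws))
    stop("rates referenced by stoichiometry without a rate law: ",
         paste(missing, collapse = ", "))
  }
  if (!all(unknown_ics %in% states)) stop("unknown_ics must be states")
  if (!all(output_map %in% states)) stop("output_map must be states")
  for (rn in names(stoichiometry)) {
    if (!all(names(stoichiometry[[rn]]) %in% states)) {
      stop("stoichiometry of rate '", rn, "' references unknown states")
    }
  }

  rate_names <- names(stoichiometry)
  smat <- matrix(0, length(states), length(rate_names),
                 dimnames = list(states, rate_names))
  for (rn in rate_names) smat[names(stoichiometry[[rn]]), rn] <-
      stoichiometry[[rn]]

  # materialize "default" rate laws as generic Michaelis-Menten forms
  rate_tags <- vapply(rate_laws[rate_names], function(f)
    if (is.character(f)) f else "custom", character(1))
  fns <- rate_laws[rate_names]
  for (rn in rate_names[rate_tags == "default"]) {
    fns[[rn]] <- make_default_rate(rn, stoichiometry[[rn]])
  }

  model <- structure(list(
    states = states,
    initial_conditions = initial_conditions,
    parameters = parameters,
    rate_laws = fns,
    rate_tags = rate_tags,
    stoichiometry = stoichiometry,
    smat = smat,
    dilution_rate = dilution_rate,
    forcing = forcing,
    unknown_ics = unknown_ics,
    output_map = output_map,
    extracellular = extracellular
  ), class = "kinetic_model")

  # smoke-check: derivatives must be finite at the declared starting point
  d0 <- tryCatch(
    model_derivatives(model, 0, pmax(initial_conditions, 0), parameters),
    error = function(e) stop("rate laws could not be evaluated at the ",
                             "initial state: ", conditionMessage(e))
  )
  if (!all(is.finite(d0))) {
    stop("derivatives are non-finite at the initial state")
  }
  model
}

make_default_rate <- function(rate_name, coefs) {
  substrates <- names(coefs)[coefs < 0]
  vmax_name <- paste0("rmax_", rate_name)
  k_names <- paste0("K_", rate_name, "_", substrates)
  force(substrates)
  function(conc, params, t) {
    r <- params[[vmax_name]]
    for (i in seq_along(substrates)) {
      cs <- conc[[substrates[i]]]
      r <- r * cs / (params[[k_names[i]]] + cs)
    }
    r
  }
}

#' Default parameter vector for generic Michaelis-Menten rate laws
#'
#' Returns the `rmax_*`/`K_*` parameters that the `"default"` rate laws of a
#' stoichiometry require, initialized at `value`.
#'
#' @param stoichiometry Named list of signed coefficient vectors (see
#'   [kinetic_model()]).
#' @param value Initial estimate for every generated parameter.
#' @param rates Which rates to generate parameters for; defaults to all.
#' @return Named numeric vector.
#' @export
default_rate_parameters <- function(stoichiometry, value = 1,
                                    rates = names(stoichiometry)) {
  out <- numeric(0)
  for (rn in rates) {
    substrates <- names(stoichiometry[[rn]])[stoichiometry[[rn]] < 0]
    nm <- c(paste0("rmax_", rn),
            if (length(substrates)) paste0("K_", rn, "_", substrates))
    out[nm] <- value
  }
  out
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model>\n")
  cat("  states:      ", length(x$states), " (",
      paste(utils::head(x$states, 6), collapse = ", "),
      if (length(x$states) > 6) ", ..." else "", ")\n", sep = "")
  cat("  rates:       ", length(x$rate_laws), "\n", sep = "")
  cat("  parameters:  ", length(x$parameters), "\n", sep = "")
  cat("  unknown ICs: ", if (length(x$unknown_ics))
    paste(x$unknown_ics, collapse = ", ") else "none", "\n", sep = "")
  cat("  measurable:  ", length(x$output_map), " states\n", sep = "")
  invisible(x)
}

#' Candidate parameter names of a model
#'
#' The candidates of the identifiability analysis are the kinetic parameters
#' plus one pseudo-parameter `ic_<state>` per unknown initial condition.
#'
#' @param model A [kinetic_model()].
#' @return Character vector.
#' @export
candidate_names <- function(model) {
  c(names(model$parameters),
    if (length(model$unknown_ics)) paste0("ic_", model$unknown_ics))
}

# Split a full candidate vector into kinetic parameters and IC overrides.
split_candidates <- function(model, parameters) {
  ic_names <- paste0("ic_", model$unknown_ics)
  list(kinetic = parameters[setdiff(names(parameters), ic_names)],
       ics = parameters[intersect(names(parameters), ic_names)])
}

model_derivatives <- function(model, t, conc, params) {
  cpos <- pmax(conc, 0)  # clip only for rate evaluation, never stored
  r <- vapply(model$rate_laws, function(f) f(cpos, params, t), numeric(1))
  d <- drop(model$smat %*% r)
  mu <- model$dilution_rate
  if (mu != 0) {
    dil <- setdiff(model$states, model$extracellular)
    d[dil] <- d[dil] - mu * conc[dil]
  }
  if (!is.null(model$forcing)) {
    fc <- model$forcing(t, cpos, params)
    d[names(fc)] <- d[names(fc)] + fc
  }
  d
}

#' Simulate a kinetic model
#'
#' Integrates the state equations with a variable-order stiff solver
#' (`deSolve::lsoda`, default tolerances rtol 1e-6 / atol 1e-9; the mixed
#' time scales of metabolic networks, with turnover on the order of seconds,
#' make the system stiff in general). Integration always starts at t = 0.
#'
#' Numerical breakdown — step-size collapse, non-finite derivatives, or a
#' trajectory dropping below `-100 * atol` — is signalled as a typed
#' integration failure (see [is_integration_failure()]) which the selection
#' procedure interprets as an estimation failure rather than a crash. States
#' are clipped at zero only when evaluating rate laws, never in the returned
#' trajectory, so pathological parameter values remain detectable.
#'
#' @param model A [kinetic_model()].
#' @param parameters Optional named vector overriding the model's parameter
#'   estimates; entries named `ic_<state>` override unknown initial
#'   conditions.
#' @param times Ascending numeric vector of output times (s).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method Integration method passed to [deSolve::ode()].
#' @return Numeric matrix with a `time` column followed by one column per
#'   state (concentrations in mM), one row per requested time.
#' @examples
#' m <- make_chain_pathway(2, seed = 1)$model
#' traj <- simulate_model(m, times = seq(0, 100, by = 20))
#' head(traj)
#' @export
simulate_model <- function(model, parameters = NULL, times,
                           rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly ascending")
  }
  if (any(times < 0)) stop("times must be non-negative")
  full <- model$parameters
  y0 <- model$initial_conditions
  if (!is.null(parameters)) {
    sp <- split_candidates(model, parameters)
    full[names(sp$kinetic)] <- sp$kinetic
    if (length(sp$ics)) {
      y0[sub("^ic_", "", names(sp$ics))] <- unname(sp$ics)
    }
  }
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  if (length(tt) == 1L) {  # only t = 0 requested: the ICs themselves
    out <- matrix(c(0, unname(y0)), nrow = 1,
                  dimnames = list(NULL, c("time", model$states)))
    return(out)
  }

  deriv <- function(t, y, p) {
    names(y) <- model$states
    d <- model_derivatives(model, t, y, p)
    if (!all(is.finite(d))) {
      stop_integration_failure(paste0("non-finite derivative at t = ", t))
    }
    list(unname(d))
  }

  out <- withCallingHandlers(
    tryCatch(
      deSolve::ode(y = unname(y0), times = tt, func = deriv, parms = full,
                   method = method, rtol = rtol, atol = atol),
      error = function(e) {
        if (is_integration_failure(e)) stop(e)
        stop_integration_failure(paste0("integration failed: ",
                                        conditionMessage(e)))
      }),
    warning = function(w) invokeRestart("muffleWarning")
  )
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop_integration_failure(paste0("integrator reported failure (istate = ",
                                    istate[1], ")"))
  }
  if (nrow(out) < length(tt) || !all(is.finite(out))) {
    stop_integration_failure("integration did not reach all requested times")
  }
  colnames(out) <- c("time", model$states)
  if (min(out[, model$states]) < -100 * atol) {
    stop_integration_failure("trajectory fell below -100 * atol: ",
                             list(min = min(out[, model$states])))
  }
  if (prepend) out <- out[-1, , drop = FALSE]
  out
}

#' Bootstrap initial estimates for unknown initial conditions
#'
#' Unknown initial concentrations cannot be left at zero during estimation:
#' zero starts can break the integration or make predictions meaningless.
#' This routine starts the unknown states at zero, integrates a single small
#' step, and returns the state values reached — strictly positive where the
#' network produces the metabolite — to be used as initial *estimates* of the
#' unknown initial conditions, which then enter the candidate vector as
#' pseudo-parameters `ic_<state>`.
#'
#' The step defaults to `1e-3` times the first observation interval when a
#' dataset is supplied, and `1e-3` s otherwise. The returned values scale
#' roughly linearly with the step (they are first-order quantities); the
#' downstream estimation refines them, so the procedure is insensitive to
#' this choice within an order of magnitude.
#'
#' @param model A [kinetic_model()] with at least one state in
#'   `unknown_ics` (an empty flag set returns an empty vector).
#' @param parameters Optional parameter overrides (see [simulate_model()]).
#' @param first_step Step size in seconds; overrides the default.
#' @param dataset Optional [kinetic_dataset()] used to derive the default
#'   step from the first observation interval.
#' @return Named numeric vector `ic_<state>` of bootstrap estimates (mM);
#'   never exactly zero.
#' @export
bootstrap_unknown_ics <- function(model, parameters = NULL, first_step = NULL,
                                  dataset = NULL) {
  if (length(model$unknown_ics) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.null(first_step)) {
    first_step <- 1e-3
    if (!is.null(dataset)) {
      tt <- sort(unique(dataset$records$time))
      dt <- diff(tt)
      dt <- dt[dt > 0]
      if (length(dt)) first_step <- 1e-3 * dt[1]
    }
  }
  zero_ics <- stats::setNames(rep(0, length(model$unknown_ics)),
                              paste0("ic_", model$unknown_ics))
  pp <- c(parameters[setdiff(names(parameters), names(zero_ics))], zero_ics)
  traj <- tryCatch(
    simulate_model(model, parameters = pp, times = c(0, first_step)),
    error = function(e) {
      if (is_integration_failure(e)) {
        stop_integration_failure(paste0(
          "bootstrap of unknown initial conditions failed from a zero ",
          "start; supply manual initial estimates for: ",
          paste(model$unknown_ics, collapse = ", ")))
      }
      stop(e)
    })
  vals <- traj[nrow(traj), model$unknown_ics]
  vals <- pmax(vals, 1e-12)  # never exactly zero
  stats::setNames(as.numeric(vals), paste0("ic_", model$unknown_ics))
}
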