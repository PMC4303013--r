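# Seeded helpers run under a local RNG state so library calls never disturb
# the caller's random stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a linear enzymatic chain pathway
#'
#' Builds a synthetic pathway \eqn{S_0 \to S_1 \to \dots \to S_n} with one
#' enzyme per step, either Michaelis-Menten (`rmax`/`K` per step, drawn
#' log-uniformly from 0.05-0.2 mM/s and 0.5-5 mM) or first-order
#' mass-action kinetics (`k` per step, 0.005-0.05 1/s). The substrate pool
#' starts at 10 mM and intermediates at zero; on those scales the dynamics
#' play out over a few hundred seconds, matching the default sampling
#' horizon of [sample_dataset()].
#'
#' Two negative-control injections are available for exercising the
#' identifiability machinery. `duplicate = TRUE` adds `rmax_v1_dup`, which
#' enters the first rate strictly additively with `rmax_v1` — a structurally
#' non-identifiable pair whose sensitivity columns are exactly parallel
#' (collinearity angle 0). `near_collinear = TRUE` adds `nc_alpha`, which
#' multiplies the first rate and leaks weakly (2 percent) into the second,
#' producing a pair whose angle sits well inside the critical band without
#' being exactly degenerate.
#'
#' @param n_enzymes Number of steps (`>= 2`).
#' @param kinetics `"michaelis_menten"` or `"mass_action"`.
#' @param seed Integer seed for the parameter draw (local RNG state).
#' @param duplicate Inject the exactly-duplicated parameter.
#' @param near_collinear Inject the near-collinear parameter.
#' @return List with `model` (a [kinetic_model()], parameters set to the
#'   generating values) and `true_parameters`.
#' @export
make_chain_pathway <- function(n_enzymes,
                               kinetics = c("michaelis_menten",
                                            "mass_action"),
                               seed = NULL, duplicate = FALSE,
                               near_collinear = FALSE) {
  stopifnot(n_enzymes >= 2)
  kinetics <- match.arg(kinetics)
  states <- paste0("S", 0:n_enzymes)
  rates <- paste0("v", seq_len(n_enzymes))
  stoich <- stats::setNames(lapply(seq_len(n_enzymes), function(i) {
    stats::setNames(c(-1, 1), states[c(i, i + 1)])
  }), rates)

  params <- with_local_seed(seed, {
    if (kinetics == "michaelis_menten") {
      vmax <- exp(stats::runif(n_enzymes, log(0.05), log(0.2)))
      km <- exp(stats::runif(n_enzymes, log(0.5), log(5)))
      p <- stats::setNames(c(vmax, km),
                           c(paste0("rmax_", rates),
                             paste0("K_", rates, "_", states[1:n_enzymes])))
      if (duplicate) p["rmax_v1_dup"] <- 0.4 * p[["rmax_v1"]]
      if (near_collinear) p["nc_alpha"] <- 1
      p
    } else {
      stats::setNames(exp(stats::runif(n_enzymes, log(0.005), log(0.05))),
                      paste0("k_", rates))
    }
  })

  laws <- vector("list", n_enzymes)
  names(laws) <- rates
  for (i in seq_len(n_enzymes)) {
    ri <- rates[i]
    si <- states[i]
    if (kinetics == "mass_action") {
      kn <- paste0("k_", ri)
      laws[[ri]] <- local({
        kn <- kn; si <- si
        function(conc, params, t) params[[kn]] * conc[[si]]
      })
    } else if (i == 1L && (duplicate || near_collinear)) {
      laws[[ri]] <- local({
        si <- si; duplicate <- duplicate; near_collinear <- near_collinear
        function(conc, params, t) {
          v <- params[["rmax_v1"]]
          if (duplicate) v <- v + params[["rmax_v1_dup"]]
          if (near_collinear) v <- v * params[["nc_alpha"]]
          v * conc[[si]] / (params[["K_v1_S0"]] + conc[[si]])
        }
      })
    } else if (i == 2L && near_collinear) {
      laws[[ri]] <- local({
        si <- si
        function(conc, params, t) {
          params[["rmax_v2"]] * (1 + 0.02 * (params[["nc_alpha"]] - 1)) *
            conc[[si]] / (params[["K_v2_S1"]] + conc[[si]])
        }
      })
    } else {
      laws[[ri]] <- "default"
    }
  }

  ics <- stats::setNames(c(10, rep(0, n_enzymes)), states)
  model <- kinetic_model(states = states, initial_conditions = ics,
                         parameters = params, rate_laws = laws,
                         stoichiometry = stoich)
  list(model = model, true_parameters = params)
}

#' Sample a noisy dataset from a model at known parameters
#'
#' Simulates the model at the generating parameter values and adds
#' independent Gaussian noise with the heteroscedastic law
#' \eqn{\sigma_{y_i} = a y_i^{true} + b} per record. Draws that would be
#' negative are resampled (zero-truncation); the number of rejected draws
#' is reported in the `truncated` attribute. States outside `mask` are
#' omitted entirely, emulating partially observed metabolomes.
#'
#' @param model A [kinetic_model()].
#' @param true_parameters Generating candidate vector (may include
#'   `ic_<state>` entries for unknown-flagged states).
#' @param times Sampling grid (s); defaults to 21 points over 0-300 s.
#' @param error_model An [error_model()]; `a = 0` gives homoscedastic noise.
#' @param mask Character vector of observed states; defaults to the model's
#'   measurable outputs.
#' @param seed Integer seed (local RNG state).
#' @return A [kinetic_dataset()] with attribute `truncated`.
#' @export
sample_dataset <- function(model, true_parameters = NULL,
                           times = seq(0, 300, length.out = 21),
                           error_model, mask = NULL, seed = NULL) {
  mask <- mask %||% model$output_map
  stopifnot(all(mask %in% model$states))
  traj <- simulate_model(model, parameters = true_parameters, times = times)
  rec <- expand.grid(time = times, variable = mask,
                     stringsAsFactors = FALSE)
  ytrue <- traj[cbind(match(rec$time, times),
                      match(rec$variable, model$states) + 1L)]
  sd <- record_sigmas(pmax(ytrue, 0), error_model)
  drawn <- with_local_seed(seed, rnorm_nonneg(length(ytrue), ytrue, sd))
  rec$value <- drawn$values
  ds <- kinetic_dataset(rec, error_model, model = model)
  attr(ds, "truncated") <- drawn$rejected
  ds
}

#' Assemble a full synthetic recovery scenario
#'
#' Wraps [make_chain_pathway()] and [sample_dataset()] into the standard
#' benchmark: a chain pathway with known generating parameters, a noisy
#' partially observed dataset, initial estimates perturbed away from the
#' truth by a log-normal factor, and optionally withheld initial conditions
#' whose states are flagged unknown in the returned model (their true
#' values are used only to generate the data). Injected negative-control
#' parameters keep their generating values as initial estimates, so the
#' recovery of their structurally entangled partners remains well defined.
#'
#' @param n_enzymes,kinetics,duplicate,near_collinear Passed to
#'   [make_chain_pathway()].
#' @param times,noise,mask Passed to [sample_dataset()] (`noise` is the
#'   [error_model()]).
#' @param withheld_ics Named numeric vector: states whose initial condition
#'   is hidden from the estimator, with their true values (e.g.
#'   `c(S1 = 2)`).
#' @param perturb_sd Standard deviation of the log-normal perturbation
#'   applied to the initial estimates (0 disables it).
#' @param seed Integer seed governing the parameter draw, the perturbation,
#'   and the measurement noise.
#' @return List of class `synthetic_scenario`: `model` (initial estimates
#'   installed, withheld ICs flagged unknown), `true_parameters` (including
#'   `ic_<state>` truths), `dataset`, `observation_mask`, `withheld_ics`,
#'   `injected` (names of injected parameters), `seed`.
#' @export
make_scenario <- function(n_enzymes = 3, kinetics = "michaelis_menten",
                          duplicate = FALSE, near_collinear = FALSE,
                          times = seq(0, 300, length.out = 21),
                          noise = error_model(0.01, 1e-6),
                          mask = NULL, withheld_ics = NULL,
                          perturb_sd = 0.3, seed = 1L) {
  chain <- make_chain_pathway(n_enzymes, kinetics, seed = seed,
                              duplicate = duplicate,
                              near_collinear = near_collinear)
  model <- chain$model
  truth <- chain$true_parameters
  injected <- intersect(c("rmax_v1_dup", "nc_alpha"), names(truth))

  if (length(withheld_ics)) {
    stopifnot(!is.null(names(withheld_ics)),
              all(names(withheld_ics) %in% model$states))
    model$initial_conditions[names(withheld_ics)] <- 0
    model$unknown_ics <- union(model$unknown_ics, names(withheld_ics))
    truth[paste0("ic_", names(withheld_ics))] <- unname(withheld_ics)
  }

  dataset <- sample_dataset(model, true_parameters = truth, times = times,
                            error_model = noise, mask = mask,
                            seed = seed + 104729L)

  init <- truth[names(model$parameters)]
  if (perturb_sd > 0) {
    free <- setdiff(names(init), injected)
    init[free] <- with_local_seed(seed + 224737L, {
      init[free] * exp(stats::rnorm(length(free), 0, perturb_sd))
    })
  }
  model$parameters <- init

  structure(list(model = model, true_parameters = truth, dataset = dataset,
                 observation_mask = mask %||% model$output_map,
                 withheld_ics = withheld_ics, injected = injected,
                 seed = seed),
            class = "synthetic_scenario")
}

#' Deterministic failure oracles for procedure dry runs
#'
#' A failure oracle is a deterministic, total rule mapping the attempt
#' context (candidate, current round, attempt index within the round, round
#' size) to success or failure; wrapped via [oracle_estimator()] it stands
#' in for the weighted-least-squares estimator in tests of the selection
#' accounting.
#'
#' `make_worst_case_oracle(nP)` fails the first `m - 1` attempts of every
#' ranking round with `m` remaining candidates and succeeds the last,
#' forcing exactly `m` attempts per round and `nP + (nP - 1) + ... + 1 =
#' nP(nP + 1)/2` attempts in total — the worst case of the one-by-one
#' selection.
#'
#' `make_random_oracle(seed, p_fail)` fails each (candidate, round) query
#' independently with probability `p_fail`, but deterministically: repeated
#' queries with the same arguments give the same answer.
#'
#' @param nP Number of candidate parameters (documentation of intent; the
#'   rule itself adapts to any round size).
#' @param seed Integer seed for the random oracle.
#' @param p_fail Marginal failure probability of the random oracle.
#' @return A function `f(context)` returning `TRUE` (success) or `FALSE`.
#' @export
make_worst_case_oracle <- function(nP = NULL) {
  function(context) context$attempt == context$round_size
}

#' @rdname make_worst_case_oracle
#' @export
make_random_oracle <- function(seed, p_fail = 0.5) {
  force(seed); force(p_fail)
  function(context) {
    key <- (seed * 7919 + context$round * 131 +
              sum(utf8ToInt(context$candidate))) %% 2147483647
    with_local_seed(as.integer(key), stats::runif(1) >= p_fail)
  }
}

#' Wrap a failure oracle as a mock estimator
#'
#' The resulting estimator never touches the model or data: it reports
#' success or failure per the oracle, leaves the parameter vector
#' unchanged, and carries the incumbent objective through, so procedure
#' traces remain well formed.
#'
#' @param oracle A failure oracle (see [make_worst_case_oracle()]).
#' @return An estimator function for [run_identifiability()].
#' @export
oracle_estimator <- function(oracle) {
  force(oracle)
  function(model, parameters, subset, dataset, control, context) {
    ok <- isTRUE(oracle(context))
    list(success = ok,
         failure_reason = if (!ok) "oracle_failure",
         parameters = parameters,
         objective = context$objective)
  }
}
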