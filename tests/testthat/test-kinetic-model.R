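test_that("zero dynamics leave the initial state untouched", {
  m <- kinetic_model(
    states = c("A", "B"),
    initial_conditions = c(A = 3, B = 0.5),
    parameters = c(p = 1),
    rate_laws = list(r1 = function(conc, params, t) 0),
    stoichiometry = list(r1 = c(A = -1, B = 1))
  )
  traj <- simulate_model(m, times = c(0, 10, 100))
  expect_equal(traj[, "A"], rep(3, 3), tolerance = 1e-8)
  expect_equal(traj[, "B"], rep(0.5, 3), tolerance = 1e-8)
})

test_that("dilution term gives exact exponential decay", {
  m <- decay_model(mu = 0.1, c0 = 1)
  traj <- simulate_model(m, times = c(0, 10), rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(traj[2, "A"]), exp(-1), tolerance = 1e-8)
})

test_that("stiff integration of the enzymatic chain matches an independent RK4", {
  ch <- make_chain_pathway(3, seed = 42)
  p <- ch$true_parameters
  vmax <- unname(p[paste0("rmax_v", 1:3)])
  km <- unname(p[paste0("K_v", 1:3, "_S", 0:2)])
  oracle <- rk4_integrate(chain_deriv_fn(vmax, km),
                          y0 = c(10, 0, 0, 0), t_end = 50, h = 0.005)
  traj <- simulate_model(ch$model, times = c(0, 50))
  expect_equal(unname(traj[2, -1]), oracle, tolerance = 1e-5)
})

test_that("finite-difference response to a rate perturbation matches the signed stoichiometry", {
  ch <- make_chain_pathway(3, seed = 5)
  m <- ch$model
  set.seed(99)
  for (i in 1:10) {
    conc <- stats::setNames(runif(4, 0.1, 5), m$states)
    base <- identestim:::model_derivatives(m, 0, conc, m$parameters)
    for (rn in names(m$stoichiometry)) {
      delta <- 1e-3
      m2 <- m
      orig <- m$rate_laws[[rn]]
      m2$rate_laws[[rn]] <- function(conc, params, t)
        orig(conc, params, t) + delta
      pert <- identestim:::model_derivatives(m2, 0, conc, m$parameters)
      diff <- (pert - base) / delta
      expected <- numeric(length(m$states))
      names(expected) <- m$states
      expected[names(m$stoichiometry[[rn]])] <- m$stoichiometry[[rn]]
      expect_equal(diff, expected, tolerance = 1e-8)
    }
  }
})

test_that("a closed chain with no dilution conserves total mass", {
  ch <- make_chain_pathway(3, seed = 8)
  traj <- simulate_model(ch$model, times = seq(0, 300, by = 30))
  totals <- rowSums(traj[, -1])
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-6)
})

test_that("integration breakdown is a typed failure, not a crash", {
  m <- kinetic_model(
    states = "A",
    initial_conditions = c(A = 1),
    parameters = c(k = 1),
    rate_laws = list(blow = function(conc, params, t) {
      params[["k"]] * conc[["A"]]^3  # finite-time blow-up
    }),
    stoichiometry = list(blow = c(A = 1))
  )
  err <- tryCatch(simulate_model(m, times = c(0, 1000)),
                  error = function(e) e)
  expect_true(is_integration_failure(err))
})

test_that("a trajectory dipping well below zero is flagged as failure", {
  m <- kinetic_model(
    states = "A",
    initial_conditions = c(A = 1),
    parameters = c(k = 1),
    rate_laws = list(drain = function(conc, params, t) params[["k"]]),
    stoichiometry = list(drain = c(A = -1))  # constant drain below zero
  )
  err <- tryCatch(simulate_model(m, times = c(0, 10)), error = function(e) e)
  expect_true(is_integration_failure(err))
})

test_that("constructor rejects inconsistent specifications", {
  expect_error(kinetic_model(
    states = "A", initial_conditions = c(A = 1), parameters = c(k = 1),
    rate_laws = list(),
    stoichiometry = list(r = c(A = 1))
  ), "without a rate law")
  expect_error(kinetic_model(
    states = "A", initial_conditions = c(A = 1), parameters = c(k = 1),
    rate_laws = list(r = function(conc, params, t) 1),
    stoichiometry = list(r = c(B = 1))
  ), "unknown states")
})

test_that("IC bootstrap from constant production is k times the step", {
  m <- const_production_model(k = 2, ic = 0, unknown = TRUE)
  boot <- bootstrap_unknown_ics(m, first_step = 1e-3)
  expect_named(boot, "ic_A")
  expect_equal(unname(boot), 2e-3, tolerance = 1e-6)
})

test_that("IC bootstrap scales first-order with the step size", {
  m <- const_production_model(k = 2, ic = 0, unknown = TRUE)
  b1 <- bootstrap_unknown_ics(m, first_step = 1e-3)
  b2 <- bootstrap_unknown_ics(m, first_step = 1e-2)
  expect_equal(unname(b2 / b1), 10, tolerance = 1e-3)
})

test_that("IC bootstrap is a no-op when every IC is known", {
  m <- const_production_model(k = 2, ic = 0, unknown = FALSE)
  boot <- bootstrap_unknown_ics(m)
  expect_length(boot, 0)
})

test_that("IC bootstrap derives its default step from the observation grid", {
  m <- const_production_model(k = 2, ic = 0, unknown = TRUE)
  em <- error_model(0, 0.1)
  ds <- kinetic_dataset(data.frame(time = c(0, 10, 20), variable = "A",
                                   value = c(0, 20, 40)), em)
  boot <- bootstrap_unknown_ics(m, dataset = ds)
  expect_equal(unname(boot), 2 * 1e-3 * 10, tolerance = 1e-6)
})
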