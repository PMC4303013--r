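# Small hand-built models and independent numerical oracles shared by the
# test files. Oracles are written from first principles (fixed-step RK4,
# forward sensitivity equations, QR projections) so they never share code
# paths with the implementation they check.

# single state with constant production dC/dt = k
const_production_model <- function(k = 2, ic = 0, unknown = FALSE) {
  kinetic_model(
    states = "A",
    initial_conditions = c(A = ic),
    parameters = c(k = k),
    rate_laws = list(gen = function(conc, params, t) params[["k"]]),
    stoichiometry = list(gen = c(A = 1)),
    unknown_ics = if (unknown) "A" else character()
  )
}

# single state with only the dilution term: dC/dt = -mu C
decay_model <- function(mu = 0.1, c0 = 1) {
  kinetic_model(
    states = "A",
    initial_conditions = c(A = c0),
    parameters = c(unused = 1),
    rate_laws = list(nil = function(conc, params, t) 0),
    stoichiometry = list(nil = c(A = 0)),
    dilution_rate = mu
  )
}

# observation y(t) = ic + theta1 * t; optionally with a redundant theta3
# entering the derivative additively (y' = theta1 + theta3)
linear_model <- function(theta1 = 3, ic = 0, unknown_ic = FALSE,
                         with_duplicate = FALSE, theta3 = 0) {
  params <- c(theta1 = theta1)
  if (with_duplicate) params["theta3"] <- theta3
  kinetic_model(
    states = "y",
    initial_conditions = c(y = ic),
    parameters = params,
    rate_laws = list(slope = function(conc, params, t) {
      params[["theta1"]] + if (with_duplicate) params[["theta3"]] else 0
    }),
    stoichiometry = list(slope = c(y = 1)),
    unknown_ics = if (unknown_ic) "y" else character()
  )
}

# independent fixed-step classical RK4 integrator
rk4_integrate <- function(deriv, y0, t_end, h = 0.01) {
  y <- y0
  t <- 0
  n <- ceiling(t_end / h)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# hand-coded Michaelis-Menten chain derivative (independent of the package's
# stoichiometry machinery): vmax, km vectors of length n
chain_deriv_fn <- function(vmax, km) {
  n <- length(vmax)
  function(t, y) {
    v <- vmax * y[seq_len(n)] / (km + y[seq_len(n)])
    d <- numeric(n + 1)
    d[1] <- -v[1]
    if (n > 1) d[2:n] <- v[seq_len(n - 1)] - v[2:n]
    d[n + 1] <- v[n]
    d
  }
}

# forward sensitivity equations for the 2-step Michaelis-Menten chain:
# states x0, x1, x2 plus d(x)/d(V1, K1, V2, K2), integrated as one
# augmented ODE system with hand-derived Jacobians.
chain2_sensitivities <- function(vmax, km, x0, times) {
  stopifnot(length(vmax) == 2, length(km) == 2)
  deriv <- function(t, y, p) {
    x <- y[1:3]
    S <- matrix(y[-(1:3)], nrow = 3)  # 3 states x 4 parameters
    v1 <- vmax[1] * x[1] / (km[1] + x[1])
    v2 <- vmax[2] * x[2] / (km[2] + x[2])
    dv1_dx0 <- vmax[1] * km[1] / (km[1] + x[1])^2
    dv2_dx1 <- vmax[2] * km[2] / (km[2] + x[2])^2
    Jx <- matrix(c(-dv1_dx0, 0, 0,
                   dv1_dx0, -dv2_dx1, 0,
                   0, dv2_dx1, 0), nrow = 3, byrow = TRUE)
    # columns: V1, K1, V2, K2
    dv1_dV1 <- x[1] / (km[1] + x[1])
    dv1_dK1 <- -vmax[1] * x[1] / (km[1] + x[1])^2
    dv2_dV2 <- x[2] / (km[2] + x[2])
    dv2_dK2 <- -vmax[2] * x[2] / (km[2] + x[2])^2
    Jp <- matrix(c(-dv1_dV1, -dv1_dK1, 0, 0,
                   dv1_dV1, dv1_dK1, -dv2_dV2, -dv2_dK2,
                   0, 0, dv2_dV2, dv2_dK2), nrow = 3, byrow = TRUE)
    dx <- c(-v1, v1 - v2, v2)
    dS <- Jx %*% S + Jp
    list(c(dx, as.vector(dS)))
  }
  y0 <- c(x0, rep(0, 12))
  out <- deSolve::ode(y = y0, times = c(0, times), func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  out <- out[match(times, out[, 1]), -1, drop = FALSE]
  list(states = out[, 1:3, drop = FALSE],
       sens = lapply(seq_len(nrow(out)), function(i) {
         matrix(out[i, -(1:3)], nrow = 3,
                dimnames = list(c("S0", "S1", "S2"),
                                c("rmax_v1", "K_v1_S0",
                                  "rmax_v2", "K_v2_S1")))
       }))
}

# residual norms after projecting candidate columns onto the span of the
# selected columns, via an independent QR decomposition
qr_residual_norms <- function(B, selected, candidates) {
  sel <- B[, selected, drop = FALSE]
  vapply(candidates, function(cn) {
    v <- B[, cn]
    if (ncol(sel)) {
      fit <- qr.fitted(qr(sel), v)
      v <- v - fit
    }
    sqrt(sum(v^2))
  }, numeric(1))
}

# noiseless dataset built directly from a trajectory
exact_dataset <- function(model, times, em, parameters = NULL,
                          mask = NULL) {
  mask <- if (is.null(mask)) model$output_map else mask
  traj <- simulate_model(model, parameters = parameters, times = times)
  rec <- expand.grid(time = times, variable = mask, stringsAsFactors = FALSE)
  rec$value <- traj[cbind(match(rec$time, times),
                          match(rec$variable, model$states) + 1L)]
  kinetic_dataset(rec, em)
}
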