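em_default <- error_model(0.1, 1e-5)

test_that("a perfect fit has zero objective", {
  m <- linear_model(theta1 = 2)
  ds <- exact_dataset(m, times = c(1, 2, 5), em_default)
  expect_equal(wls_objective(m, m$parameters, ds), 0, tolerance = 1e-10)
})

test_that("the objective matches hand arithmetic on a single record", {
  # y_E = 2, y_C = 3, sigma = 0.1 * 2 + 1e-5 = 0.20001, S = (1/sigma)^2
  m <- linear_model(theta1 = 3, ic = 0)
  ds <- kinetic_dataset(data.frame(time = 1, variable = "y", value = 2),
                        em_default)
  expect_equal(wls_objective(m, c(theta1 = 3), ds), (1 / 0.20001)^2,
               tolerance = 1e-6)
  expect_equal(wls_objective(m, c(theta1 = 3), ds), 24.9975,
               tolerance = 1e-3)
})

test_that("doubling both error coefficients quarters the objective", {
  m <- linear_model(theta1 = 3)
  rec <- data.frame(time = c(1, 3), variable = "y", value = c(2.5, 10))
  S1 <- wls_objective(m, m$parameters,
                      kinetic_dataset(rec, error_model(0.1, 1e-5)))
  S2 <- wls_objective(m, m$parameters,
                      kinetic_dataset(rec, error_model(0.2, 2e-5)))
  expect_equal(S2, S1 / 4, tolerance = 1e-10)
})

test_that("noiseless linear data recover slope and intercept exactly", {
  truth <- linear_model(theta1 = 2, ic = 1)
  times <- c(0, 1, 2, 4, 8)
  ds <- exact_dataset(truth, times, em_default)
  m <- linear_model(theta1 = 0.7, ic = 0, unknown_ic = TRUE)
  res <- estimate_subset(m, c(theta1 = 0.7, ic_y = 0.2),
                         subset = c("theta1", "ic_y"), ds)
  expect_true(res$success)
  expect_equal(unname(res$estimated_values["theta1"]), 2, tolerance = 1e-6)
  expect_equal(unname(res$estimated_values["ic_y"]), 1, tolerance = 1e-6)
  expect_lt(res$objective, 1e-8)
})

test_that("a structurally duplicated parameter pair fails with a singular FIM", {
  truth <- linear_model(theta1 = 2, ic = 1)
  ds <- exact_dataset(truth, c(0, 1, 2, 4), em_default)
  m <- linear_model(theta1 = 1, ic = 1, with_duplicate = TRUE, theta3 = 1)
  entry <- c(theta1 = 1, theta3 = 1)
  res <- estimate_subset(m, entry, subset = c("theta1", "theta3"), ds)
  expect_false(res$success)
  expect_identical(res$failure_reason, "singular_fim")
  expect_identical(res$parameters, entry)  # rolled back
})

test_that("failure rolls the parameter vector back to its entry state", {
  truth <- linear_model(theta1 = 2, ic = 0)
  ds <- exact_dataset(truth, c(1, 2, 4), em_default)
  m <- linear_model(theta1 = 5, ic = 0, with_duplicate = TRUE, theta3 = 5)
  entry <- c(theta1 = 5, theta3 = 5)
  res <- estimate_subset(m, entry, subset = c("theta1", "theta3"), ds)
  expect_false(res$success)
  expect_identical(res$parameters, entry)
})

test_that("subset estimation leaves frozen parameters untouched", {
  ch <- make_chain_pathway(2, seed = 3)
  em <- error_model(0.01, 1e-6)
  ds <- sample_dataset(ch$model, times = seq(0, 300, length.out = 15),
                       error_model = em, seed = 5)
  entry <- ch$true_parameters * c(1.3, 1, 1, 1)
  res <- estimate_subset(ch$model, entry, subset = "rmax_v1", ds)
  expect_true(res$success)
  frozen <- setdiff(names(entry), "rmax_v1")
  expect_identical(res$parameters[frozen], entry[frozen])
  expect_lte(res$objective, res$objective_entry)
})

test_that("scalar FIM reduces to the closed form sigma over sensitivity", {
  s <- 2.5; sig <- 0.2; theta <- c(p = 4)
  fi <- compute_fim(matrix(s, 1, 1), sig, theta)
  expect_equal(unname(fi$fim[1, 1]), s^2 / sig^2, tolerance = 1e-12)
  sigma_theta <- sqrt(fi$covariance[1, 1])
  expect_equal(unname(sigma_theta), sig / abs(s), tolerance = 1e-12)
  expect_equal(unname(fi$normalized_std), sig / abs(s) / 4,
               tolerance = 1e-12)
})

test_that("orthogonal sensitivity columns give a diagonal FIM", {
  B <- cbind(c(1, 0, 0, 0), c(0, 2, 0, 0))
  fi <- compute_fim(B, rep(0.5, 4), c(a = 1, b = 1))
  expect_equal(unname(fi$fim[1, 2]), 0, tolerance = 1e-12)
  expect_equal(unname(fi$covariance[1, 2]), 0, tolerance = 1e-12)
})

test_that("FIM times covariance is the identity on random well-posed cases", {
  set.seed(77)
  for (i in 1:10) {
    B <- matrix(rnorm(30 * 4), 30, 4)
    theta <- stats::setNames(runif(4, 0.5, 2), paste0("p", 1:4))
    fi <- compute_fim(B, runif(30, 0.1, 1), theta)
    expect_false(fi$singular)
    prod <- fi$fim %*% fi$covariance
    expect_equal(unname(prod), diag(4), tolerance = 1e-8)
    expect_equal(fi$fim, t(fi$fim), tolerance = 1e-10)
  }
})

test_that("a rank-deficient sensitivity block raises the singular signal without inversion", {
  B <- cbind(c(1, 2, 3), c(2, 4, 6))
  fi <- compute_fim(B, rep(1, 3), c(a = 1, b = 1))
  expect_true(fi$singular)
  expect_null(fi$covariance)
})

test_that("parameter recovery on the chain is within reported uncertainty", {
  # data generated at known parameters; estimate the three Vmax values
  n_ok <- 0
  for (seed in 1:8) {
    ch <- make_chain_pathway(3, seed = 300 + seed)
    em <- error_model(0.01, 1e-6)
    ds <- sample_dataset(ch$model, times = seq(0, 300, length.out = 21),
                         error_model = em, seed = 600 + seed)
    subset <- paste0("rmax_v", 1:3)
    res <- estimate_subset(ch$model, ch$true_parameters, subset, ds)
    if (isTRUE(res$success)) {
      z <- abs(res$estimated_values - ch$true_parameters[subset]) /
        (res$normalized_std * abs(res$estimated_values))
      if (all(z <= 3)) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 7)
})
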