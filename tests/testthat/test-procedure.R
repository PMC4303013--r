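all_success_estimator <- oracle_estimator(function(context) TRUE)

test_that("with an always-succeeding estimator every candidate is selected in nP attempts", {
  tr <- run_identifiability(NULL, NULL, candidates = paste0("p", 1:4),
                            estimator = all_success_estimator)
  expect_equal(tr$evaluation_count, 4L)
  expect_setequal(tr$selected, paste0("p", 1:4))
  expect_length(tr$evaluated, 0L)
  expect_length(tr$nonselected, 0L)
})

test_that("the worst-case failure pattern forces the triangular attempt count", {
  tr <- run_identifiability(NULL, NULL, candidates = c("a", "b", "c"),
                            estimator = oracle_estimator(
                              make_worst_case_oracle(3)))
  expect_equal(tr$evaluation_count, 6L)
  expect_setequal(tr$selected, c("a", "b", "c"))

  tr1 <- run_identifiability(NULL, NULL, candidates = "solo",
                             estimator = oracle_estimator(
                               make_worst_case_oracle(1)))
  expect_equal(tr1$evaluation_count, 1L)

  tr5 <- run_identifiability(NULL, NULL, candidates = paste0("p", 1:5),
                             estimator = oracle_estimator(
                               make_worst_case_oracle(5)))
  expect_equal(tr5$evaluation_count, sum(5:1))
})

test_that("failed candidates are recycled after every success and can then succeed", {
  # fail candidate 'a' until at least two parameters are selected
  oracle <- function(context) {
    if (context$candidate == "a") length(context$selected) >= 2 else TRUE
  }
  tr <- run_identifiability(NULL, NULL, candidates = c("a", "b", "c"),
                            estimator = oracle_estimator(oracle))
  expect_setequal(tr$selected, c("a", "b", "c"))
  # a fails round 1; b succeeds (a recycled); a fails round 2; c succeeds;
  # a succeeds round 3 -> 5 attempts
  expect_equal(tr$evaluation_count, 5L)
  expect_identical(
    tr$iterations$outcome,
    c("failure", "success", "failure", "success", "success"))
})

test_that("the attempt count respects the triangular bound for random failure patterns", {
  for (nP in c(3, 5, 10)) {
    for (s in 1:10) {
      tr <- run_identifiability(
        NULL, NULL, candidates = paste0("p", seq_len(nP)),
        estimator = oracle_estimator(make_random_oracle(s * 17 + nP)))
      expect_lte(tr$evaluation_count, nP * (nP + 1) / 2)
      expect_length(tr$nonselected, 0L)
      expect_setequal(c(tr$selected, tr$evaluated), paste0("p", seq_len(nP)))
    }
  }
})

test_that("identical inputs give byte-identical traces", {
  est <- oracle_estimator(make_random_oracle(99))
  tr1 <- run_identifiability(NULL, NULL, candidates = paste0("p", 1:6),
                             estimator = est)
  tr2 <- run_identifiability(NULL, NULL, candidates = paste0("p", 1:6),
                             estimator = est)
  expect_identical(tr1$iterations, tr2$iterations)
  expect_identical(tr1$selected, tr2$selected)
})

test_that("first-failure mode stops at the first failed inclusion", {
  tr <- run_identifiability(NULL, NULL, candidates = c("a", "b", "c"),
                            mode = "first_failure",
                            estimator = oracle_estimator(
                              make_worst_case_oracle(3)))
  expect_equal(tr$evaluation_count, 1L)
  expect_length(tr$selected, 0L)

  tr_ok <- run_identifiability(NULL, NULL, candidates = c("a", "b"),
                               mode = "first_failure",
                               estimator = all_success_estimator)
  expect_setequal(tr_ok$selected, c("a", "b"))
})

test_that("with no failures the intensive and first-failure modes coincide", {
  int <- run_identifiability(NULL, NULL, candidates = paste0("p", 1:4),
                             estimator = all_success_estimator)
  cmp <- compare_baseline(int, NULL, NULL,
                          estimator = all_success_estimator)
  expect_equal(cmp$n_selected_intensive, cmp$n_selected_first_failure)
  expect_identical(cmp$first_failure$iterations$candidate,
                   int$iterations$candidate)
})

test_that("the procedure runs end to end on a kinetic scenario and improves the fit", {
  sc <- make_scenario(n_enzymes = 2, seed = 71, perturb_sd = 0.2,
                      times = seq(0, 300, length.out = 13))
  tr <- run_identifiability(sc$model, sc$dataset)
  expect_length(tr$nonselected, 0L)
  expect_lt(tr$final_objective, tr$initial_objective)
  # objective is non-increasing across successful iterations
  succ <- tr$iterations[tr$iterations$outcome == "success", ]
  expect_true(all(diff(succ$objective_after) <= 1e-8))
  rep <- selection_report(tr)
  expect_true(all(rep$normalized_std > 0, na.rm = TRUE))
})

test_that("both canonical error-model settings complete and improve their own objectives", {
  for (em in list(error_model(1e-1, 1e-5), error_model(1e-2, 1e-6))) {
    sc <- make_scenario(n_enzymes = 2, seed = 83, perturb_sd = 0.2,
                        times = seq(0, 300, length.out = 13), noise = em)
    tr <- run_identifiability(sc$model, sc$dataset)
    expect_length(tr$nonselected, 0L)
    expect_lte(tr$final_objective, tr$initial_objective)
  }
})

test_that("an unsimulable starting vector aborts before any selection", {
  m <- kinetic_model(
    states = "A", initial_conditions = c(A = 1), parameters = c(k = 1),
    rate_laws = list(blow = function(conc, params, t)
      params[["k"]] * conc[["A"]]^3),
    stoichiometry = list(blow = c(A = 1)))
  em <- error_model(0.1, 1e-5)
  ds <- kinetic_dataset(data.frame(time = 500, variable = "A", value = 2),
                        em)
  expect_error(run_identifiability(m, ds), "not simulable")
})
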