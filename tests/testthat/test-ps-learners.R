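test_that("score truncation clamps elementwise", {
  expect_equal(truncate_scores(0, 0.01), 0.01)
  expect_equal(truncate_scores(0.5, 0.01), 0.5)
  x <- c(0, 0.005, 0.3, 0.999, 1)
  expect_equal(truncate_scores(x, 0.025), pmin(pmax(x, 0.025), 0.975))
  expect_error(truncate_scores(x, 0.5))
})

test_that("fully regularized treatment model collapses to the marginal rate", {
  co <- noise_outcome_cohort(n = 300, seed = 1)
  fit <- fit_lasso_ps(co, fast_ctl, seed = 1, lambda = 1e6)
  expect_length(fit$coefficients, 0)
  expect_equal(unique(round(fit$scores, 10)), round(mean(co$A), 10),
               tolerance = 1e-6)
})

test_that("CV lasso is conservative under independence and finds real signal", {
  co <- noise_outcome_cohort(n = 500, p = 15, seed = 2)
  fit <- fit_lasso_ps(co, fast_ctl, seed = 2)
  expect_lte(length(fit$coefficients), 6)
  expect_lt(max(abs(fit$scores - mean(co$A))), 0.2)
  expect_true(all(fit$scores >= 0.01 & fit$scores <= 0.99))

  # one strongly predictive covariate dominates the coefficients
  set.seed(3)
  n <- 600
  w1 <- rbinom(n, 1, 0.5)
  W <- cbind(w1 = w1, w2 = rbinom(n, 1, 0.3), w3 = rbinom(n, 1, 0.3))
  A <- rbinom(n, 1, plogis(-2 + 4 * w1))
  co2 <- cohort_data(W, A, rbinom(n, 1, 0.2))
  fit2 <- fit_lasso_ps(co2, fast_ctl, seed = 3)
  expect_equal(names(which.max(abs(fit2$coefficients))), "w1")

  expect_error(fit_lasso_ps(cohort_data(W, rep(1L, n), rbinom(n, 1, 0.2))),
               "arm")
})

test_that("outcome-adaptive lasso forces outcome-selected covariates in", {
  set.seed(4)
  n <- 600
  W <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
              dimnames = list(NULL, paste0("w", 1:6)))
  A <- rbinom(n, 1, plogis(-0.5 + 0.8 * W[, 1]))
  Y <- rbinom(n, 1, plogis(-2 + 2.5 * W[, 3]))
  co <- cohort_data(W, A, Y)
  fit <- fit_outcome_adaptive_ps(co, fast_ctl, seed = 4)
  expect_equal(fit$model_id, 2L)
  # bookkeeping: active set mapped to penalty weight 0, all else 1
  expect_true(fit$penalty_weights[["w3"]] == 0)
  expect_true(all(fit$penalty_weights[names(fit$penalty_weights) != "w3" &
                                        fit$penalty_weights == 0] == 0))

  # at a lambda large enough to zero every weight-1 column, the forced
  # column keeps a nonzero coefficient
  pf <- ifelse(colnames(W) == "w3", 0, 1)
  big <- fit_lasso_ps(co, fast_ctl, seed = 4, penalty_factor = pf, lambda = 10)
  expect_true("w3" %in% names(big$coefficients))
  expect_true(all(setdiff(paste0("w", 1:6), "w3") %in%
                    setdiff(paste0("w", 1:6), names(big$coefficients))))
})

test_that("collaborative lambda selection scans the recorded criterion", {
  co <- noise_outcome_cohort(n = 300, seed = 5)
  q <- fit_initial_outcome(co, fast_ctl, seed = 5)

  # path of length 1: that lambda is returned
  g1 <- matrix(truncate_scores(rep(mean(co$A), 300), 0.01), ncol = 1)
  sel1 <- collab_select_lambda(0.2, g1, co, q, fast_ctl, seed = 5)
  expect_equal(sel1$lambda, 0.2)

  # identical candidate scores at every lambda: losses tie exactly and the
  # largest (most regularized) lambda wins
  gmat <- g1[, c(1, 1, 1)]
  tie <- collab_select_lambda(c(0.3, 0.2, 0.1), gmat, co, q, fast_ctl, seed = 5)
  expect_equal(tie$lambda, 0.3)
  expect_equal(length(unique(tie$criterion_values)), 1)

  # oracle equivalence: selection is the brute-force argmin of the recorded
  # criterion values (first index on the decreasing path)
  fit3 <- fit_collab_ps(co, q, fast_ctl, seed = 5)
  expect_equal(fit3$model_id, 3L)
  idx <- which(fit3$lambda_path == fit3$selected_lambda)
  expect_equal(idx, unname(which.min(fit3$criterion_values)))
  expect_true(fit3$selected_lambda %in% fit3$lambda_path)
})

test_that("model nesting holds under an empty outcome active set", {
  co <- noise_outcome_cohort(n = 400, seed = 1)
  # premise: the outcome lasso selects nothing on pure-noise outcomes
  expect_length(blindps:::outcome_active_set(co, fast_ctl, seed = 1), 0)
  m1 <- fit_lasso_ps(co, fast_ctl, seed = 1)
  m2 <- fit_outcome_adaptive_ps(co, fast_ctl, seed = 1)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$selected_lambda, m2$selected_lambda)

  q <- fit_initial_outcome(co, fast_ctl, seed = 1)
  m3 <- fit_collab_ps(co, q, fast_ctl, seed = 1)
  m4 <- fit_collab_oal_ps(co, q, fast_ctl, seed = 1)
  expect_identical(m3$scores, m4$scores)
  expect_identical(m3$selected_lambda, m4$selected_lambda)
})

test_that("cross-fitting produces out-of-fold scores reproducibly", {
  co <- tiny_cohort(n = 300, seed = 8, censoring_rate = 0)
  ctl2 <- ps_control(cv_folds = 5, crossfit_folds = 2)
  cf <- crossfit_ps(co, 1, ctl2, seed = 8)
  expect_equal(cf$model_id, 5L)
  expect_false(anyNA(cf$scores))
  expect_length(unique(cf$crossfit_fold_assignment), 2)

  # same seed, same folds
  cf2 <- crossfit_ps(co, 1, ctl2, seed = 8)
  expect_identical(cf$crossfit_fold_assignment, cf2$crossfit_fold_assignment)
  expect_identical(cf$scores, cf2$scores)

  # out-of-fold contract: refitting the base learner on fold-2 rows from
  # scratch reproduces fold-1 scores bit-exactly
  folds <- cf$crossfit_fold_assignment
  train <- which(folds != 1)
  held <- which(folds == 1)
  tr <- cohort_data(co$W[train, , drop = FALSE], co$A[train], co$Y[train])
  base <- fit_lasso_ps(tr, ctl2, seed = derive_seed(8, "fold_fit", 1))
  manual <- drop(predict(base$.fit, newx = as(co$W[held, , drop = FALSE],
                                              "CsparseMatrix"),
                         s = base$selected_lambda, type = "response"))
  manual <- truncate_scores(manual, ctl2$truncation)
  expect_identical(unname(cf$scores[held]), unname(manual))

  # a fold with a single treatment arm is an error naming the arm problem
  skew <- cohort_data(co$W, c(1L, rep(0L, 299)), co$Y)
  expect_error(crossfit_ps(skew, 1, ctl2, seed = 8), "arm")
})

test_that("all eight models emit truncated scores via the dispatcher", {
  co <- tiny_cohort(n = 250, seed = 9, censoring_rate = 0, target_outcome_rate = 0.2)
  ctl2 <- ps_control(cv_folds = 4, crossfit_folds = 2, collab_folds = 3)
  for (m in 1:8) {
    fit <- fit_ps(co, m, ctl2, seed = 9)
    expect_equal(fit$model_id, m)
    expect_true(all(fit$scores >= ctl2$truncation &
                      fit$scores <= 1 - ctl2$truncation))
    if (m >= 5) expect_length(fit$crossfit_fold_assignment, 250)
    if (m < 5) expect_null(fit$crossfit_fold_assignment)
  }
})
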