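test_that("complete-case restriction drops exactly the censored rows", {
  set.seed(1)
  W <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  C <- rep(1L, 100); C[1:4] <- 0L
  Y <- rbinom(100, 1, 0.3); Y[C == 0] <- NA
  co <- cohort_data(W, rbinom(100, 1, 0.5), Y, C)
  cc <- complete_case(co)
  expect_equal(length(cc$A), 96)
  expect_false(anyNA(cc$Y))

  all_obs <- cohort_data(W, co$A, rbinom(100, 1, 0.3), rep(1L, 100))
  expect_identical(complete_case(all_obs), all_obs)
  all_cens <- cohort_data(W, co$A, rep(NA_integer_, 100), rep(0L, 100))
  expect_error(complete_case(all_cens), "all rows censored")
})

test_that("fully regularized outcome model returns arm-specific rates", {
  co <- noise_outcome_cohort(n = 500, seed = 2)
  q <- fit_initial_outcome(co, fast_ctl, seed = 2, lambda = 1e6)
  expect_equal(unique(round(q$Q1, 8)), round(mean(co$Y[co$A == 1]), 8),
               tolerance = 1e-3)
  expect_equal(unique(round(q$Q0, 8)), round(mean(co$Y[co$A == 0]), 8),
               tolerance = 1e-3)
  expect_true(all(q$Q1 > 0 & q$Q1 < 1 & q$Q0 > 0 & q$Q0 < 1))
  co_one_class <- cohort_data(co$W, co$A, rep(0L, 500))
  expect_error(fit_initial_outcome(co_one_class), "both outcome classes")
})

test_that("CV outcome lasso recovers a sparse logistic support", {
  set.seed(3)
  n <- 5000; p <- 30
  W <- matrix(rbinom(n * p, 1, 0.4), n, p,
              dimnames = list(NULL, paste0("w", 1:p)))
  A <- rbinom(n, 1, 0.4)
  truth <- paste0("w", 1:5)
  eta <- -2.5 + W[, 1:5] %*% c(1, -1, 1, -1, 1) + 0.3 * A
  Y <- rbinom(n, 1, plogis(eta))
  q <- fit_initial_outcome(cohort_data(W, A, Y), fast_ctl, seed = 3)
  recovered <- intersect(truth, names(q$coefficients))
  expect_gte(length(recovered), 4)
})

test_that("targeting solves the efficient-score equation", {
  toy <- toy_table()
  fl <- fluctuate(toy$q, toy$g, toy$data)
  # Q already solves the score equation: epsilon stays at 0
  expect_equal(fl$epsilon, 0)
  expect_lt(abs(fl$score_residual), 1e-10)

  co <- tiny_cohort(n = 500, seed = 4, censoring_rate = 0)
  g <- fit_lasso_ps(co, fast_ctl, seed = 4)
  q <- fit_initial_outcome(co, fast_ctl, seed = 4)
  fl2 <- fluctuate(q, g, co)
  expect_lt(abs(fl2$score_residual), 1e-8)
})

test_that("TMLE equals hand g-computation on the two-stratum toy table", {
  toy <- toy_table()
  res <- estimate_ate(toy$data, toy$g, q = toy$q)
  expect_equal(res$psi_hat, toy$psi, tolerance = 1e-10)
  expect_lt(abs(res$eif_mean), 1e-8)
  expect_equal(res$ci_upper - res$psi_hat, res$psi_hat - res$ci_lower,
               tolerance = 1e-12)
  expect_equal(res$ci_upper - res$ci_lower, 2 * 1.96 * res$standard_error,
               tolerance = 1e-12)
})

test_that("with known g = 1/2 and marginal Q, TMLE reduces to the unadjusted RD", {
  # equal arms make the reduction exact
  set.seed(5)
  n <- 400
  A <- rep(c(1L, 0L), each = n / 2)
  W <- matrix(rbinom(2 * n, 1, 0.5), n, 2, dimnames = list(NULL, c("u", "v")))
  Y <- rbinom(n, 1, plogis(-1.5 + 0.5 * W[, 1] + 0.3 * A))
  co <- cohort_data(W, A, Y)
  q_marg <- outcome_fit(rep(mean(Y), n), rep(mean(Y), n))
  res <- estimate_ate(co, rep(0.5, n), q = q_marg)
  unadj <- unadjusted_rd(co)
  expect_equal(res$psi_hat, unadj$psi_hat, tolerance = 1e-8)

  # randomized data, rich Q: adjusted and unadjusted agree within one SE
  res2 <- estimate_ate(co, rep(0.5, n), control = fast_ctl, seed = 5)
  expect_lt(abs(res2$psi_hat - unadj$psi_hat), unadj$standard_error)
})

test_that("null plasmode designs give estimates near zero", {
  co <- tiny_cohort(n = 600, seed = 6, censoring_rate = 0)
  des <- auto_design(co, treatment_effect = 0, n_per_replicate = 1000,
                     n_replicates = 3, seed = 6)
  for (r in run_replicates(co, des)) {
    g <- fit_lasso_ps(r$data, fast_ctl, seed = 6)
    res <- estimate_ate(r$data, g, control = fast_ctl, seed = 6)
    expect_lt(abs(res$psi_hat), 4 * res$standard_error)
    expect_lt(abs(res$eif_mean), 1e-8)
  }
})

test_that("unadjusted risk difference matches the textbook Wald interval", {
  co <- cohort_data(cbind(w = rep(0, 20), z = rep(1, 20)),
                    rep(c(1L, 0L), each = 10),
                    c(rep(c(1L, 0L), c(2, 8)), rep(c(1L, 0L), c(1, 9))))
  res <- unadjusted_rd(co)
  expect_equal(res$psi_hat, 0.1)
  se <- sqrt(0.2 * 0.8 / 10 + 0.1 * 0.9 / 10)
  expect_equal(res$standard_error, se)
  expect_equal(res$ci_lower, 0.1 - 1.96 * se)

  equal <- cohort_data(cbind(w = rep(0, 8), z = rep(1, 8)),
                       rep(c(1L, 0L), each = 4), rep(c(1L, 0L, 0L, 0L), 2))
  expect_equal(unadjusted_rd(equal)$psi_hat, 0)
  one_arm <- cohort_data(cbind(w = rep(0, 6), z = rep(1, 6)),
                         rep(1L, 6), rep(0L, 6))
  expect_error(unadjusted_rd(one_arm), "arm")
})
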