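test_that("intercept calibration matches closed forms and a bisection oracle", {
  expect_equal(calibrate_intercept(rep(0, 50), 0.25), qlogis(0.25), tolerance = 1e-8)
  expect_equal(calibrate_intercept(rep(0, 50), 0.5), 0, tolerance = 1e-8)

  set.seed(11)
  lp <- rnorm(1e5)
  a <- calibrate_intercept(lp, 0.04)
  expect_lt(abs(mean(plogis(a + lp)) - 0.04), 1e-6)

  # independent bisection oracle over the intercept
  lo <- -20; hi <- 20
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (mean(plogis(mid + lp)) < 0.04) lo <- mid else hi <- mid
  }
  expect_equal(a, (lo + hi) / 2, tolerance = 1e-6)

  expect_error(calibrate_intercept(c(0, Inf), 0.3), "calibration failure")
})

test_that("cohort generation is deterministic and hits its marginal targets", {
  spec <- cohort_spec(n_subjects = 20000, n_investigator_covariates = 10,
                      n_proxy_features = 40, target_treatment_prevalence = 0.364,
                      seed = 1)
  co <- generate_cohort(spec)
  expect_identical(co, generate_cohort(spec))

  # realized rates within 3 binomial MC standard errors of the targets
  se_a <- sqrt(0.364 * (1 - 0.364) / 20000)
  expect_lt(abs(mean(co$A) - 0.364), 3 * se_a)
  se_y <- sqrt(0.042 * (1 - 0.042) / sum(co$C))
  expect_lt(abs(mean(co$Y[co$C == 1]) - 0.042), 3 * se_y)
  se_c <- sqrt(0.04 * 0.96 / 20000)
  expect_lt(abs(mean(co$C == 0) - 0.04), 3 * se_c)
})

test_that("zero confounding yields a randomized treatment", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 8000, n_investigator_covariates = 4, n_proxy_features = 30,
    confounding_strengths = 0, target_treatment_prevalence = 0.5, seed = 3
  ))
  expect_lt(abs(mean(co$A) - 0.5), 3 * sqrt(0.25 / 8000))
  cors <- abs(cor(co$A, co$W))
  expect_lt(max(cors), 4.5 / sqrt(8000))
})

test_that("censoring is controlled and MCAR", {
  co0 <- generate_cohort(cohort_spec(300, censoring_rate = 0, seed = 5,
                                     n_proxy_features = 10))
  expect_true(all(co0$C == 1))
  expect_false(anyNA(co0$Y))

  # chi-square p-values for C vs A approximately uniform across seeds
  pvals <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(2000, n_proxy_features = 10,
                                      censoring_rate = 0.2, seed = s))
    suppressWarnings(chisq.test(table(co$C, co$A))$p.value)
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("prevalence screening drops exactly the rare binary columns", {
  n <- 2000
  set.seed(9)
  rare <- sapply(1:30, function(j) sample(c(1, rep(0, n - 1))))       # 0.0005
  common <- sapply(1:70, function(j) sample(rep(c(1, 0), c(20, n - 20)))) # 0.01
  cont <- matrix(rnorm(n), n, 1)
  W <- cbind(rare, common, cont)
  colnames(W) <- c(sprintf("r%02d", 1:30), sprintf("c%02d", 1:70), "cont")
  co <- cohort_data(W, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))

  sc <- screen_prevalence(co, 0.001)
  expect_equal(ncol(sc$W), 71)  # 70 common binaries + untouched continuous
  expect_identical(colnames(sc$W), c(sprintf("c%02d", 1:70), "cont"))

  expect_identical(screen_prevalence(co, 0)$W, co$W)

  zero_col <- cohort_data(cbind(z = rep(0, 10), k = rep(1, 10)),
                          rep(c(0, 1), 5), rep(c(0, 1), 5))
  expect_identical(colnames(screen_prevalence(zero_col, 0.001)$W), "k")
})

test_that("cohort summary reproduces one-decimal percentages from counts", {
  s <- summarize_cohort_counts(21343, 7767, 899)
  expect_equal(s$pct, c(36.4, 63.6, 4.2))
  expect_equal(s$n, c(7767, 13576, 899))
})

test_that("cohort CSV round-trips, with Y empty where censored", {
  co <- tiny_cohort(n = 120, seed = 8, censoring_rate = 0.2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort_csv(co, path)
  # censored outcomes are empty fields in the file
  header <- readLines(path, n = 1)
  expect_match(header, "^id,A,Y,C,")
  back <- read_cohort_csv(path)
  expect_equal(unname(back$W), unname(co$W))
  expect_identical(back$A, co$A)
  expect_identical(back$Y, co$Y)
  expect_identical(back$C, co$C)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(100, target_treatment_prevalence = 0))
  expect_error(cohort_spec(100, censoring_rate = 1))
  expect_error(cohort_spec(100, proxy_noise = 0.5))
  expect_error(cohort_data(cbind(a = 1:3), c(0, 1, 1), c(0, NA, 1), c(1, 1, 1)),
               "Y may be missing only where C = 0")
})
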