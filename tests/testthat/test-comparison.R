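test_that("perfect linearity gives rho 1 and the exact OLS line", {
  x <- 1:10
  y <- 2 * x + 1
  pr <- pearson_regression(x, y)
  expect_equal(pr$rho, 1)
  expect_equal(pr$slope, 2)
  expect_equal(pr$intercept, 1)
  expect_lt(pr$p, 1e-10)
})

test_that("rho agrees with the sums formula and is symmetric and affine-invariant", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 3, 5, 4)
  pr <- pearson_regression(x, y)
  n <- 5
  sums <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pr$rho, sums, tolerance = 1e-12)
  expect_equal(pearson_regression(y, x)$rho, pr$rho, tolerance = 1e-12)
  expect_equal(pearson_regression(3 * x + 7, 0.5 * y - 2)$rho, pr$rho,
               tolerance = 1e-12)
  # degenerate input: zero variance reported as missing, not an error
  expect_true(is.na(pearson_regression(rep(1, 5), y)$rho))
})

test_that("independent normals give near-zero correlation at large n", {
  set.seed(17)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(pearson_regression(x, y)$rho), 0.05)
})

test_that("Bland-Altman closed cases and antisymmetry", {
  x <- c(3, 5, 8, 13)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  ba <- bland_altman(x, x + 3)
  expect_equal(ba$bias, -3)
  expect_equal(ba$sd, 0)
  expect_equal(ba$loa_low, -3)
  expect_equal(ba$loa_high, -3)
  y <- c(4, 4, 9, 12)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  expect_equal(bland_altman(x, y, loa_multiplier = 1)$loa_high,
               bland_altman(x, y)$bias + bland_altman(x, y)$sd)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman SD recovers the difference SD at n = 10^4", {
  set.seed(23)
  x <- rnorm(1e4)
  y <- x - rnorm(1e4) # differences ~ N(0, 1)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$sd - 1), 0.03)
  expect_lt(abs(ba$bias), 0.03)
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # a=20 exposed events, b=10 exposed non-events, c=10, d=20
  outcome <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  predictor <- c(rep(1, 30), rep(0, 30))
  f <- logistic_fit(outcome, predictor)
  expect_equal(f$or_, 4.0, tolerance = 1e-6)
  expect_equal(f$coef, log(4), tolerance = 1e-6)
  expect_true(f$converged)
  expect_true(f$ci95[1] < 4 && 4 < f$ci95[2])
  expect_error(logistic_fit(rep(1, 20), rnorm(20)), "single class")
})

test_that("planted logistic coefficient is recovered", {
  set.seed(29)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(-1 + 0.8 * x))
  f <- logistic_fit(y, x)
  expect_lt(abs(f$coef - 0.8), 0.1)
  expect_true(f$converged)
})

test_that("separation is flagged, not silently reported", {
  x <- c(rnorm(15, -3), rnorm(15, 3))
  y <- c(rep(0, 15), rep(1, 15))
  f <- logistic_fit(y, x)
  expect_false(f$converged)
})

test_that("agreement battery has the full pair x parameter x column layout", {
  records <- identical_method_records(n_patients = 8)
  out <- run_agreement_battery(records)
  # 6 pairs x 3 parameters x 3 absolute timepoints = 54 absolute cells
  expect_equal(sum(!startsWith(out$column, "d")), 54L)
  # plus 6 x 3 x 2 delta columns
  expect_equal(nrow(out), 54L + 36L)
  abs_rows <- out[out$column %in% c("PET1", "PET2"), ]
  expect_true(all(abs(abs_rows$rho - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(abs_rows$bias == 0, na.rm = TRUE))
  # PET3 is all-zero by construction: flagged, not fabricated
  pet3 <- out[out$column == "PET3", ]
  expect_true(all(is.na(pet3$rho)))
  expect_true(all(pet3$note == "zero variance"))
  expect_true("p_bh" %in% names(out))
})

test_that("DS regression battery recovers a planted burden effect and flags bad cells", {
  set.seed(41)
  n <- 40
  mtv <- runif(n, 20, 500)
  # planted: larger baseline burden raises the odds of a poor DS, with
  # enough overlap that the fit does not separate
  poor <- runif(n) < plogis((mtv - 250) / 80)
  ds <- ifelse(poor, sample(3:5, n, replace = TRUE),
               sample(1:2, n, replace = TRUE))
  rows <- list()
  for (i in seq_len(n)) for (tp in c("PET1", "PET3")) {
    fac <- if (tp == "PET1") 1 else 0.1
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = sprintf("P%02d", i), timepoint = tp, method = "v25",
      suvmean = 4 * fac, mtv_ml = mtv[i] * fac, tlg = 4 * mtv[i] * fac^2,
      ds = if (tp == "PET3") ds[i] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  out <- run_ds_regression(records, parameters = "mtv_ml", cuts = 2:5)
  abs2 <- out[out$variant == "absolute" & out$cut == 2, ]
  # response (DS <= 2) is less likely at high MTV: OR < 1 and significant
  expect_lt(abs2$or_, 1)
  expect_lt(abs2$p, 0.05)
  # zero-variance predictor cells are reported with a reason
  expect_true(all(out$note[out$variant == "delta"] != "" |
                  is.finite(out$p[out$variant == "delta"])))
})

test_that("DS regression reports single-class cells like the dashes of a table", {
  records <- identical_method_records(n_patients = 12)
  records$ds[records$timepoint == "PET3"] <- 1L # everyone responds
  out <- run_ds_regression(records, parameters = "mtv_ml", cuts = 2:3)
  expect_true(all(out$note == "single-class outcome"))
  expect_true(all(is.na(out$or_)))
})

test_that("null calibration: type-I error of both tests is near nominal", {
  set.seed(53)
  n_rep <- 2000
  p_pearson <- replicate(n_rep, pearson_regression(rnorm(25), rnorm(25))$p)
  rate_p <- mean(p_pearson < 0.05)
  expect_gte(rate_p, 0.03)
  expect_lte(rate_p, 0.07)
  p_wald <- replicate(n_rep, {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) NA_real_ else logistic_fit(y, rnorm(60))$p
  })
  rate_w <- mean(p_wald < 0.05, na.rm = TRUE)
  expect_gte(rate_w, 0.03)
  expect_lte(rate_w, 0.07)
})
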