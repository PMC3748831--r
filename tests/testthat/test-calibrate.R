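test_that("OLS recovers exact lines and validates inputs", {
  x <- c(1, 2, 3, 5, 8)
  cv <- fit_ols(x, 2 * x + 1)
  expect_equal(cv$slope, 2, tolerance = 1e-12)
  expect_equal(cv$intercept, 1, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)
  expect_identical(cv$n_points, 5L)
  expect_error(fit_ols(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_ols(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_ols(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("OLS matches the normal-equations closed form and residual-sum R^2", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:120, 1)
    x <- rnorm(n, sd = 3)
    y <- 0.7 * x - 2 + rnorm(n, sd = 0.5)
    cv <- fit_ols(x, y)
    # closed form from the normal equations
    slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(cv$slope, slope, tolerance = 1e-9)
    expect_equal(cv$intercept, intercept, tolerance = 1e-9)
    ss_res <- sum((y - intercept - slope * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    expect_equal(cv$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-9)
  }
})

test_that("robust fit equals OLS on outlier-free data and resists outliers", {
  x <- seq(0, 5, length.out = 20)
  y <- x
  ols <- fit_ols(x, y)
  rob <- fit_robust(x, y)
  expect_equal(rob$slope, ols$slope, tolerance = 1e-9)
  expect_equal(rob$intercept, ols$intercept, tolerance = 1e-9)
  expect_true(rob$converged)

  y_out <- y
  y_out[7] <- y[7] + 5
  rob <- fit_robust(x, y_out)
  ols <- fit_ols(x, y_out)
  # Theil-Sen median-slope oracle: unaffected by one outlier
  ts <- median(unlist(lapply(1:19, function(i)
    (y_out[-(1:i)] - y_out[i]) / (x[-(1:i)] - x[i]))))
  expect_lt(abs(rob$slope - 1), 0.05)
  expect_gt(abs(ols$slope - 1), abs(rob$slope - 1))
  expect_lt(abs(rob$slope - ts), abs(ols$slope - ts) + 1e-9)
})

test_that("max_iter = 0 returns the OLS start flagged non-converged", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 8)
  rob <- fit_robust(x, y, max_iter = 0)
  ols <- fit_ols(x, y)
  expect_equal(rob$slope, ols$slope)
  expect_equal(rob$intercept, ols$intercept)
  expect_false(rob$converged)
})

test_that("Huber IRLS agrees with an independent M-estimator implementation", {
  skip_if_not_installed("MASS")
  set.seed(29)
  x <- runif(60, 0, 6)
  y <- 1.4 * x + 0.3 + rnorm(60, sd = 0.3)
  y[sample(60, 6)] <- y[sample(60, 6)] + rnorm(6, 8, 1)
  rob <- fit_robust(x, y, tol = 1e-10, max_iter = 200)
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 200,
                   acc = 1e-10)
  expect_equal(rob$slope, unname(coef(ref)[2]), tolerance = 0.01)
  expect_equal(rob$intercept, unname(coef(ref)[1]), tolerance = 0.05)
})

test_that("calibration fits known mpe on fpkm with zero-exclusion", {
  design <- generate_spikein_design(10, 3)
  # fpkm exactly proportional to known mpe: slope 1, intercept -log10(c)
  const <- 0.02
  fpkm <- setNames(const * design$known_mpe, design$spike_id)
  cv <- calibrate(fpkm, design, method = "ols")
  expect_equal(cv$slope, 1, tolerance = 1e-9)
  expect_equal(cv$intercept, -log10(const), tolerance = 1e-9)
  expect_identical(cv$n_points, 10L)

  fpkm[3] <- 0
  cv <- calibrate(fpkm, design, method = "ols")
  expect_identical(cv$n_points, 9L)

  expect_error(calibrate(setNames(rep(0, 10), design$spike_id), design),
               "too few detected spike-ins: 0 of 10|too few")
})

test_that("calibration works from an expression matrix per sample", {
  design <- generate_spikein_design(8, 3)
  lengths <- c(setNames(rep(1000, 8), design$spike_id), T1 = 1000)
  cts <- data.frame(transcript_id = rep(c(design$spike_id, "T1"), 2),
                    sample_id = rep(c("s0", "s1"), each = 9),
                    count = rep(c(design$known_mpe * 0.1, 50), 2))
  mat <- build_expression_matrix(cts, lengths)
  curves <- calibrate_all(mat, design, method = "ols")
  expect_named(curves, c("s0", "s1"))
  expect_equal(curves$s0$slope, 1, tolerance = 1e-9)
  mat <- add_mpe(mat, curves)
  mpe <- SummarizedExperiment::assay(mat, "mpe")
  # round trip: spike fpkm maps back to its known concentration
  expect_equal(unname(mpe[design$spike_id, "s0"]), design$known_mpe,
               tolerance = 1e-6)
  ct <- curve_table(curves)
  expect_identical(nrow(ct), 2L)
  expect_true(all(ct$r_squared >= 0 & ct$r_squared <= 1))
})

test_that("MPE prediction maps through the curve and is monotone", {
  cv <- standard_curve(1, 0, "log10", "ols")
  expect_equal(predict_mpe(cv, 100), 100)
  expect_equal(predict_mpe(cv, 0), 0)
  cv <- standard_curve(0.9, 0.5, "log10", "ols")
  expect_equal(predict_mpe(cv, 10), 10^1.4)
  lin <- standard_curve(2, -5, "linear", "ols")
  expect_equal(predict_mpe(lin, 1), 0)   # clipped at zero
  expect_equal(predict_mpe(lin, 10), 15)
  set.seed(33)
  f <- sort(c(0, 10^runif(50, -3, 4)))
  for (curve in list(cv, lin)) {
    expect_true(all(diff(predict_mpe(curve, f)) >= 0))
  }
  expect_error(predict_mpe(cv, -1), "non-negative")
})
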