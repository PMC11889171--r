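test_that("B-factor ratio and its propagated SE", {
  r <- bfactor_ratio(1390, 160, 417, 30)
  expect_equal(r$ratio, 1390 / 417, tolerance = 1e-12)
  expect_equal(r$ratio, 3.33, tolerance = 1e-2)
  expect_equal(r$sigma,
               (1390 / 417) * sqrt((160 / 1390)^2 + (30 / 417)^2),
               tolerance = 1e-12)
  expect_equal(r$sigma, 0.45, tolerance = 1e-2)
  same <- bfactor_ratio(300, 0, 300, 0)
  expect_equal(same$ratio, 1)
  expect_equal(same$sigma, 0)
  expect_error(bfactor_ratio(300, 10, 0, 10), class = "fib_format_error")
})

test_that("ratio of a group with itself has SE sigma*sqrt(2)/B", {
  r <- bfactor_ratio(320, 15, 320, 15)
  expect_equal(r$ratio, 1)
  expect_equal(r$sigma, 15 * sqrt(2) / 320, tolerance = 1e-12)
})

test_that("resolution extrapolation from an anchored published row", {
  fit <- anchored_fit_from_bfactor(1390, 160, 1243, 15.8)
  ex <- extrapolate_resolution(fit, 5000)
  # closed-form oracle: y* = 1/15.8^2 + (2/1390) ln(5000/1243)
  y_star <- 1 / 15.8^2 + (2 / 1390) * log(5000 / 1243)
  expect_equal(ex$resolution_A, 1 / sqrt(y_star), tolerance = 1e-12)
  expect_equal(ex$resolution_A, 12.9, tolerance = 0.05)
  sm <- 2 * 160 / 1390^2
  expect_equal(ex$sigma_y, sm * log(5000), tolerance = 1e-12)
  expect_equal(ex$sigma, ex$sigma_y / (2 * y_star^1.5), tolerance = 1e-12)
  # extrapolating to the anchor returns the anchor resolution exactly
  at_anchor <- extrapolate_resolution(
    anchored_fit_from_bfactor(1390, 0, 1243, 15.8), 1243)
  expect_equal(at_anchor$resolution_A, 15.8, tolerance = 1e-9)
})

test_that("extrapolation beyond validity errors", {
  fit <- structure(list(slope = 0.001, intercept = -0.2, se_slope = 0,
                        se_intercept = 0, n_points = 4, r_squared = 1),
                   class = "linear_fit")
  expect_error(extrapolate_resolution(fit, 5000),
               class = "fib_extrapolation_error")
})

test_that("resolution differences combine errors in quadrature", {
  d <- resolution_difference(12.9, 0.8, 7.6, 0.3)
  expect_equal(d$delta, 5.3, tolerance = 1e-12)
  expect_equal(d$sigma, sqrt(0.8^2 + 0.3^2), tolerance = 1e-12)
  expect_equal(resolution_difference(7, 0, 7, 0)$delta, 0)
  expect_equal(resolution_difference(7, 0, 6, 0)$sigma, 0)
  # antisymmetry under swapping group and control
  fwd <- resolution_difference(12.9, 0.8, 7.6, 0.3)
  rev <- resolution_difference(7.6, 0.3, 12.9, 0.8)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$sigma, rev$sigma)
})

test_that("noiseless exponential decay is recovered to 1e-6", {
  x <- seq(7.5, 57.5, by = 5)
  y <- 22.4 * exp(-0.185 * x) + 0.0568
  fit <- fit_exponential_decay(x, y, rep(0.01, length(x)))
  expect_true(fit$converged)
  expect_equal(fit$A, 22.4, tolerance = 1e-6)
  expect_equal(fit$k, 0.185, tolerance = 1e-6)
  expect_equal(fit$c, 0.0568, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("decay fit rejects degenerate inputs", {
  x <- seq(5, 50, by = 5)
  expect_error(fit_exponential_decay(x[1:3], 1:3, rep(1, 3)),
               class = "fib_insufficient_particles")
  expect_error(fit_exponential_decay(x, rep(2, length(x)),
                                     rep(0.1, length(x))),
               "no decay", class = "fib_format_error")
  expect_error(fit_exponential_decay(x, exp(-x), rep(0, length(x))),
               class = "fib_format_error")
})

test_that("weights matter: precise points dominate the decay fit", {
  x <- seq(7.5, 57.5, by = 5)
  y <- 10 * exp(-0.2 * x) + 0.5
  y_noisy <- y
  y_noisy[1] <- y[1] * 1.5  # corrupt the shallowest point
  se <- rep(0.01, length(x))
  se[1] <- 100              # but give it negligible weight
  fit <- fit_exponential_decay(x, y_noisy, se)
  expect_equal(fit$k, 0.2, tolerance = 1e-3)
})

test_that("Spearman trend handles ties and matches cor.test when tie-free", {
  expect_equal(spearman_trend(c(1, 2, 5, 9))$r, 1)
  expect_equal(spearman_trend(c(9, 7, 3, 1))$r, -1)
  # reference backside B-factors (rounded): tied 321s get average ranks
  ref <- c(321, 284, 321, 311, 299)
  tr <- spearman_trend(ref)
  expect_equal(tr$r, -3 / sqrt(9.5 * 10), tolerance = 1e-12)
  expect_equal(tr$r, -0.31, tolerance = 0.01)
  # tie-free case against R's estimator
  v <- c(3.2, 1.1, 5.4, 2.2, 9.9, 0.5, 4.4)
  ct <- suppressWarnings(cor.test(v, seq_along(v), method = "spearman"))
  tr2 <- spearman_trend(v)
  expect_equal(tr2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(tr2$p_value, ct$p.value, tolerance = 1e-9)
  expect_error(spearman_trend(c(1, 2)),
               class = "fib_insufficient_particles")
})

test_that("backside summary reports extremes and trend", {
  s <- backside_group_summary(c(321, 284, 321, 311, 299))
  expect_equal(s$min_B, 284)
  expect_equal(s$max_B, 321)
  expect_equal(s$spearman_r, -3 / sqrt(95), tolerance = 1e-12)
  one <- backside_group_summary(c(300, 300))
  expect_equal(one$min_B, one$max_B)
})

test_that("amorphous length divides area by the perpendicular extent", {
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 0.5, 0.5))
  expect_equal(amorphous_length(rect, milling_axis = "y"), 0.5)
  lshape <- cbind(c(0, 8, 8, 4, 4, 0), c(0, 0, 1, 1, 0.5, 0.5))
  expect_equal(amorphous_length(lshape, milling_axis = "y"), 6 / 8)
  expect_error(amorphous_length(cbind(c(0, 1), c(0, 1))),
               class = "fib_format_error")
  bowtie <- cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))
  expect_error(amorphous_length(bowtie), "self-intersecting",
               class = "fib_format_error")
})

test_that("Welch comparison from summary statistics", {
  res <- compare_length_groups(list(mean = 0.5, sd = 0.07, n = 5),
                               list(mean = 0.79, sd = 0.18, n = 21))
  va <- 0.07^2 / 5; vb <- 0.18^2 / 21
  t_oracle <- (0.5 - 0.79) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 / (va^2 / 4 + vb^2 / 20)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(abs(res$t), 5.77, tolerance = 0.01)
  expect_equal(res$df, df_oracle, tolerance = 1e-12)
  expect_equal(res$df, 17.7, tolerance = 0.05)
})

test_that("raw-value comparison matches t.test and identical groups give t = 0", {
  a <- c(0.4, 0.5, 0.55, 0.48, 0.52)
  b <- c(0.7, 0.9, 0.75, 0.8, 0.85, 0.77)
  res <- compare_length_groups(a, b)
  tt <- t.test(a, b)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  same <- compare_length_groups(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(compare_length_groups(a, 0.5),
               class = "fib_insufficient_particles")
})

test_that("closed-form SEs agree with 1e5-draw Monte-Carlo propagation", {
  set.seed(77)
  n <- 1e5
  # ratio
  Bg <- 1390; sg <- 30; Bc <- 417; sc <- 10
  mc <- rnorm(n, Bg, sg) / rnorm(n, Bc, sc)
  closed <- bfactor_ratio(Bg, sg, Bc, sc)$sigma
  expect_lt(abs(sd(mc) - closed) / sd(mc), 0.03)
  # predicted y at x = ln 5000 (exact for a linear map)
  m <- 0.002; sm <- 2e-5; c0 <- 0.003; sc0 <- 2e-4; x <- log(5000)
  mc_y <- rnorm(n, m, sm) * x + rnorm(n, c0, sc0)
  expect_lt(abs(sd(mc_y) - sqrt((sm * x)^2 + sc0^2)) / sd(mc_y), 0.03)
  # resolution from y (delta method)
  y0 <- m * x + c0; sy <- sqrt((sm * x)^2 + sc0^2)
  mc_res <- 1 / sqrt(rnorm(n, y0, sy))
  expect_lt(abs(sd(mc_res) - sy / (2 * y0^1.5)) / sd(mc_res), 0.03)
  # difference in quadrature
  mc_d <- rnorm(n, 12.9, 0.8) - rnorm(n, 7.6, 0.3)
  expect_lt(abs(sd(mc_d) - sqrt(0.8^2 + 0.3^2)) / sd(mc_d), 0.03)
})
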