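test_that("shot-noise variance matches the brute-force oracle", {
  set.seed(1)
  for (cv in c(0, 0.5)) {
    mc <- shot_noise_mc(70, 500, 3, 500, cv)
    expect_lt(abs(shot_noise_variance(70, 500, 3, 500, cv) - mc["mean"]),
              3 * mc["se"])
  }
})

test_that("shot-noise variance has the stated structure", {
  # quadratic in the mean amplitude, linear in the event count
  expect_equal(shot_noise_variance(140, 500, 3, 500, 0.5),
               4 * shot_noise_variance(70, 500, 3, 500, 0.5))
  expect_equal(shot_noise_variance(70, 1000, 3, 500, 0.5),
               2 * shot_noise_variance(70, 500, 3, 500, 0.5))
  expect_error(shot_noise_variance(70, 500, 3, 0), "interval")
  expect_warning(shot_noise_variance(70, 500, 60, 500), "validity")
})

test_that("the finite-window approximation error grows with tau/T", {
  set.seed(2)
  rel_err <- vapply(c(0.002, 0.02, 0.08), function(r) {
    interval <- 400
    tau <- r * interval
    mc <- shot_noise_mc(10, 400, tau, interval, 0, reps = 150,
                        dt = min(0.5, tau / 4))
    abs(shot_noise_variance(10, 400, tau, interval, 0) - mc["mean"]) /
      mc["mean"]
  }, numeric(1))
  expect_lt(rel_err[1], 0.05)
  expect_true(rel_err[3] > rel_err[1])
})

test_that("Gaussian threshold-linear rate: closed form vs special cases", {
  # at threshold the rate is beta * sigma / sqrt(2 pi)
  expect_equal(rate_threshold_linear(2, 1.5, 2, beta = 3),
               3 * 1.5 / sqrt(2 * pi))
  # deep suprathreshold: linear asymptote
  expect_equal(rate_threshold_linear(102, 1, 2, beta = 2), 2 * 100,
               tolerance = 1e-10)
  # degenerate sigma = 0
  expect_equal(rate_threshold_linear(5, 0, 2, beta = 2), 6)
  expect_equal(rate_threshold_linear(1, 0, 2, beta = 2), 0)
})

test_that("Gaussian threshold-linear rate matches the Monte-Carlo mean", {
  set.seed(3)
  grid <- expand.grid(i_mean = c(-0.5, 0, 0.8), sigma = c(0.5, 2),
                      theta = c(0, 1))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    x <- rnorm(2e6, g$i_mean, g$sigma)
    mc <- pmax(x - g$theta, 0)
    se <- sd(mc) / sqrt(length(mc))
    expect_lt(abs(rate_threshold_linear(g$i_mean, g$sigma, g$theta) -
                    mean(mc)), 3 * se)
  }
})

test_that("rate is monotone in its drive and fluctuations below threshold", {
  i <- seq(-1, 3, by = 0.25)
  f <- rate_threshold_linear(i, 1, 0.5)
  expect_true(all(diff(f) > 0))
  # below threshold, larger fluctuations help
  f_sigma <- rate_threshold_linear(0, c(0.5, 1, 2), 1)
  expect_true(all(diff(f_sigma) > 0))
})

test_that("amplification factor: homogeneity, invariances and quadrature oracle", {
  # theta = 0: exact homogeneity of degree one => ratio k
  expect_equal(amplification_factor(0.3, 1, 0, 1.7), 1.7)
  expect_equal(amplification_factor(5, 0.2, 0, 3), 3)
  # far above threshold the ratio approaches k
  expect_equal(amplification_factor(1e5, 1, 1, 1.7), 1.7, tolerance = 1e-4)
  # invariant to joint rescaling of (i_mean, sigma, theta)
  expect_equal(amplification_factor(0.5, 1, 2, 1.7),
               amplification_factor(5, 10, 20, 1.7))
  # quadrature oracle at theta/sigma = 2, i/sigma = 0.5, k = 1.7
  oracle <- function(mu, s, th) {
    integrate(function(x) (x - th) * dnorm(x, mu, s), th, Inf,
              rel.tol = 1e-12)$value
  }
  expect_equal(amplification_factor(0.5, 1, 2, 1.7),
               oracle(1.7 * 0.5, 1.7, 2) / oracle(0.5, 1, 2),
               tolerance = 1e-8)
  expect_error(amplification_factor(-10, 0.1, 5, 2), "zero")
})

test_that("amplification sweep is flat away from threshold and k at k = 1", {
  sw1 <- amplification_sweep(k = 1)
  expect_true(all(abs(sw1$ratio - 1) < 1e-12))
  sw <- amplification_sweep(k = 1.7)
  # normalised ratio near one for suprathreshold-leaning excitability
  flat <- sw[sw$theta_over_sigma <= 0.5, ]
  expect_true(all(abs(flat$ratio_norm - 1) < 0.08))
  # the input-strength dependence grows as threshold moves away
  spread <- sw |>
    dplyr::group_by(.data$theta_over_sigma) |>
    dplyr::summarise(spread = max(abs(.data$ratio_norm - 1)))
  up <- spread[spread$theta_over_sigma >= 0, ]
  expect_true(all(diff(up$spread) > 0))
  # the mean amplification grows with the threshold distance: suprathreshold
  # baselines (theta < 0) amplify less than k, subthreshold ones more
  rowm <- dplyr::distinct(sw, .data$theta_over_sigma, .data$row_mean)
  rowm <- rowm[order(rowm$theta_over_sigma), ]
  expect_true(all(diff(rowm$row_mean[rowm$theta_over_sigma >= 0]) > 0))
  expect_true(all(rowm$row_mean[rowm$theta_over_sigma < 0] < 1.7))
  expect_true(all(rowm$row_mean[rowm$theta_over_sigma > 0] > 1.7))
})

test_that("bump spike probabilities follow the Poisson-window mapping", {
  sw <- bump_probability_sweep()
  expect_true(all(sw$p_after >= sw$p_before - 1e-12))
  expect_true(all(sw$p_before >= 0 & sw$p_after <= 1))
  # zero rate -> zero probability
  deep <- bump_probability_sweep(i_over_sigma = -50, theta_over_sigma = 3.7)
  expect_true(all(deep$p_before < 1e-12))
  # infinite window -> probability one wherever the rate is positive
  wide <- bump_probability_sweep(window = 1e9)
  expect_true(all(wide$p_after[wide$rate_after > 0] > 1 - 1e-9))
  # near-threshold bumps gain the most; deeply subthreshold bumps stay
  # quiet after amplification
  mid <- sw[sw$p_before > 0.4 & sw$p_before < 0.6, ]
  expect_true(nrow(mid) > 0)
  expect_true(all(mid$p_after > 0.65))
  expect_gt(mean(mid$p_after - mid$p_before), 0.2)
  deep2 <- sw[sw$p_before < 0.01, ]
  expect_true(all(deep2$p_after < 0.35))
})
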