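test_that("blocker effect ratios are identities on equal or scaled phases", {
  x <- c(8, 9.5, 11, 13, 7.2, 10.1)
  eq <- blocker_effect(x, x)
  expect_equal(eq$y_mean, 1)
  expect_equal(eq$y_sd, 1)
  sc <- blocker_effect(2 * x, x)
  expect_equal(sc$y_mean, 2)
  expect_equal(sc$y_sd, 2)
  expect_error(blocker_effect(1, x), "at least 2")
  # zero-variance post flagged undefined
  z <- blocker_effect(x, rep(5, 6))
  expect_true(z$undefined)
})

test_that("blocker effect on a mixture pair matches the forward expectation", {
  p <- make_blocker_pair(amplitude_model(), x = 0.65, a = 2,
                         n_pre = 1e5, n_post = 1e5, seed = 9)
  ph <- pair_phases(p)
  eff <- blocker_effect(ph$pre, ph$post)
  expect_lt(abs(eff$y_mean - 1.65), 0.02)
})

test_that("affected fraction inverts the blocker-effect formula", {
  expect_equal(affected_fraction(1.65, 2)$x, 0.65)
  expect_equal(affected_fraction(1.0, 2)$x, 0)
  expect_equal(affected_fraction(1.73, 2)$x, 0.73)
  expect_equal(affected_fraction(1.47, 2)$x, 0.47)
  # general inversion: x = (y - 1)/(a - 1) for a = 3
  expect_equal(affected_fraction(2.0, 3)$x, 0.5)
  out <- affected_fraction(c(0.8, 2.4), 2)
  expect_true(all(out$clipped))
  expect_equal(out$x, c(0, 1))
  expect_error(affected_fraction(1.5, 1), "a")
})

test_that("affected-fraction estimator recovers the generating fraction", {
  m <- amplitude_model()
  for (x in seq(0.1, 0.9, by = 0.2)) {
    p <- make_blocker_pair(m, x = x, a = 2, n_pre = 1e4, n_post = 1e4,
                           seed = round(1000 * x))
    ph <- pair_phases(p)
    xhat <- affected_fraction(mean(ph$pre) / mean(ph$post), 2)$x
    # 3 MC standard errors of the ratio-based estimator at n = 1e4
    cv <- sd(ph$post) / mean(ph$post)
    se <- cv * sqrt(2 / 1e4) * (1 + x)   # delta-method scale, generous
    expect_lt(abs(xhat - x), max(3 * se, 0.03))
  }
})

test_that("two-means clustering separates affected from unaffected cells", {
  set.seed(5)
  eff <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:24),
    y_mean = c(rnorm(12, 1.05, 0.05), rnorm(12, 1.6, 0.05)),
    y_sd = c(rnorm(12, 1.05, 0.05), rnorm(12, 1.6, 0.05)))
  cl <- cluster_effects(eff)
  expect_gt(cl$mean_silhouette, 0.6)
  truth <- rep(c("non-affected", "affected"), each = 12)
  expect_gte(mean(cl$labels$cluster == truth), 0.95)
  expect_equal(cl$centroids$cluster[which.max(cl$centroids$y_mean)],
               "affected")
  # degenerate identical points
  dg <- cluster_effects(tibble::tibble(y_mean = rep(1, 5), y_sd = rep(1, 5)))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$mean_silhouette))
  expect_error(cluster_effects(eff[1:3, ]), "at least 4")
})

test_that("single-blob data yields low silhouettes over repeated draws", {
  sil <- vapply(1:40, function(s) {
    set.seed(s)
    eff <- tibble::tibble(y_mean = rnorm(20, 1.3, 0.15),
                          y_sd = rnorm(20, 1.3, 0.15))
    cluster_effects(eff, seed = s)$mean_silhouette
  }, numeric(1))
  expect_lt(median(sil), 0.55)
})

test_that("distribution curves are normalised histograms on a fixed grid", {
  one <- distribution_curve(5.4, bin_width = 1)
  expect_equal(sum(one$rel_freq), 1)
  expect_equal(one$rel_freq[length(one$rel_freq)], 1)
  set.seed(2)
  u <- runif(1e5, 0, 10)
  cu <- distribution_curve(u, bin_width = 1, max_amplitude = 10)
  expect_true(all(abs(cu$rel_freq[1:10] - 0.1) < 0.01))
  # doubling all amplitudes moves mass to doubled bin centers exactly
  x <- c(1.2, 3.4, 3.6, 7.9, 9.1)
  c1 <- distribution_curve(x, bin_width = 1)
  c2 <- distribution_curve(2 * x, bin_width = 2)
  expect_equal(c2$rel_freq, c1$rel_freq)
  expect_equal(c2$bin_center, 2 * c1$bin_center)
  expect_error(distribution_curve(numeric(0)), "no events")
})

test_that("cell-averaged curves weight every cell equally", {
  ev <- tibble::tibble(
    cell_id = rep(c("a", "b"), c(10, 1000)),
    amplitude_pA = c(rep(2.5, 10), rep(7.5, 1000)))
  avg <- average_distribution_curve(ev, bin_width = 5)
  expect_equal(sum(avg$rel_freq), 1)
  expect_equal(avg$rel_freq[avg$bin_center == 2.5], 0.5)
})

test_that("multiplicative reversal restores the pre distribution; wrong models do not", {
  m <- amplitude_model()
  p <- make_blocker_pair(m, x = 0.6, a = 2, n_pre = 500, n_post = 500,
                         seed = 21)
  ph <- pair_phases(p)
  # x = 0 leaves post untouched; x = 1 doubles everything
  r0 <- reverse_blocker(ph$pre, ph$post, "multiplicative", x = 0, seed = 1,
                        n_perm = 199)
  expect_equal(r0$reconstructed, ph$post)
  r1 <- reverse_blocker(ph$pre, ph$post, "multiplicative", x = 1, seed = 1,
                        n_perm = 199)
  expect_equal(r1$reconstructed, 2 * ph$post)

  mult_p <- additive_p <- triple_p <- numeric(25)
  add_ratio <- numeric(25)
  for (s in 1:25) {
    p <- make_blocker_pair(m, x = 0.6, a = 2, n_pre = 600, n_post = 600,
                           seed = 500 + s)
    ph <- pair_phases(p)
    mult_p[s] <- reverse_blocker(ph$pre, ph$post, "multiplicative",
                                 n_perm = 199, seed = s)$p_value
    ra <- reverse_blocker(ph$pre, ph$post, "additive", n_perm = 199,
                          seed = s)
    additive_p[s] <- ra$p_value
    add_ratio[s] <- ra$mean_ratio
    triple_p[s] <- reverse_blocker(ph$pre, ph$post, "triple", n_perm = 199,
                                   seed = s)$p_value
  }
  # the true model reverses the distribution; the negative controls
  # restore only the mean
  expect_gte(mean(mult_p > 0.01), 0.95)
  expect_gte(mean(additive_p < 0.01), 0.9)
  expect_gte(mean(triple_p < 0.01), 0.9)
  expect_lt(abs(mean(add_ratio) - 1), 0.02)
})

test_that("doubling-based group reconstructions behave at the extremes", {
  m <- amplitude_model()
  naive <- sample_cell_events(m, 800, seed = 31)$amplitude_pA
  target <- 2 * sample_cell_events(m, 800, seed = 32)$amplitude_pA
  res <- naive_doubling_reconstruction(naive, target, n_perm = 199,
                                       seed = 1)
  expect_gt(res$p_value, 0.01)
  # against the undoubled naive distribution the difference is obvious
  res2 <- naive_doubling_reconstruction(naive, naive, n_perm = 199,
                                        seed = 1)
  expect_lt(res2$p_value, 0.01)

  means <- c(8, 9, 10, 11, 12, 13, 14, 15)
  r0 <- reconstruct_group_curve(means, fraction = 0, n_boot = 3, seed = 1)
  expect_equal(unique(r0$replicates$cell_mean), sort(means))
  r1 <- reconstruct_group_curve(means, fraction = 1, factor = 2,
                                n_boot = 3, seed = 1)
  expect_equal(unique(r1$replicates$cell_mean), sort(2 * means))
})

test_that("cumulative-curve reconstruction is self-consistent on cohorts", {
  ok <- 0L
  for (s in 1:20) {
    pop <- generate_population(c(naive = 20, trained = 20),
                               amplified_fraction = 0.35, seed = 600 + s)
    cm <- dplyr::summarise(dplyr::group_by(pop, .data$cell_id, .data$group),
                           m = mean(.data$amplitude_pA), .groups = "drop")
    rec <- reconstruct_group_curve(cm$m[cm$group == "naive"],
                                   fraction = 0.35, factor = 2,
                                   target_cell_means =
                                     cm$m[cm$group == "trained"],
                                   n_boot = 5, seed = s)
    if (median(rec$ks$p_value) > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})
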