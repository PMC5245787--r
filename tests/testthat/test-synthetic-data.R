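test_that("amplitude model: samples respect the floor and match the analytic mean", {
  m <- amplitude_model()
  x <- sample_cell_events(m, 2e4, seed = 1)$amplitude_pA
  expect_true(all(x > 0))
  expect_true(all(x >= m$detection_floor))
  expect_lt(abs(mean(x) - mean(m)) / mean(m), 0.02)

  # tail_weight = 0 reduces to the truncated-Gaussian body
  m0 <- amplitude_model(tail_weight = 0)
  x0 <- sample_cell_events(m0, 2e4, seed = 2)$amplitude_pA
  expect_true(all(x0 <= m0$tail_start))
  expect_lt(abs(mean(x0) - mean(m0)) / mean(m0), 0.02)
})

test_that("tail mass above the strong/weak cut follows the binomial oracle", {
  m <- amplitude_model()          # naive-like: body 8 pA, tail above 13 pA
  n <- 200
  k <- sum(sample_cell_events(m, n, seed = 3)$amplitude_pA > m$tail_start)
  # binomial oracle: mean n*w, 3-sigma band
  se3 <- 3 * sqrt(n * m$tail_weight * (1 - m$tail_weight))
  expect_lt(abs(k - n * m$tail_weight), se3)
})

test_that("amplification multiplies the same base draws under a fixed seed", {
  m <- amplitude_model()
  x1 <- sample_cell_events(m, 500, amplification = 1, seed = 7)$amplitude_pA
  x2 <- sample_cell_events(m, 500, amplification = 2, seed = 7)$amplitude_pA
  expect_equal(x2, 2 * x1)
  expect_error(sample_cell_events(m, 0), "positive")
  expect_error(sample_cell_events(m, 10, amplification = 0.5), "amplification")
})

test_that("blocker pairs realise both generative conventions", {
  m <- amplitude_model()
  # x = 0: the two phases share a distribution
  p0 <- make_blocker_pair(m, x = 0, a = 2, n_pre = 400, n_post = 400,
                          seed = 1)
  ph <- pair_phases(p0)
  expect_gt(ks_two_sample(ph$pre, ph$post)$p_value, 0.001)
  # x = 1, a = 2 mixture-on-pre: ratio of means -> 2
  p1 <- make_blocker_pair(m, x = 1, a = 2, n_pre = 2e4, n_post = 2e4,
                          seed = 2)
  ph1 <- pair_phases(p1)
  expect_lt(abs(mean(ph1$pre) / mean(ph1$post) - 2), 0.05)
  # x = 0.65: expected mean ratio (1 - x) + x a = 1.65
  p65 <- make_blocker_pair(m, x = 0.65, a = 2, n_pre = 1e5, n_post = 1e5,
                           seed = 3)
  ph65 <- pair_phases(p65)
  expect_lt(abs(mean(ph65$pre) / mean(ph65$post) - 1.65), 0.02)
  # fully-doubled-pre: pre is 2x base; post mixes blocked events back down
  pf <- make_blocker_pair(m, x = 0.65, a = 2, n_pre = 1e5, n_post = 1e5,
                          convention = "fully-doubled-pre", seed = 4)
  phf <- pair_phases(pf)
  expected <- 2 / (0.65 * 1 + 0.35 * 2)   # pre/post mean ratio
  expect_lt(abs(mean(phf$pre) / mean(phf$post) - expected), 0.03)
  expect_error(make_blocker_pair(m, x = 1.2, a = 2), "x")
})

test_that("population generator flags amplified cells and is seed-deterministic", {
  pop1 <- generate_population(c(naive = 6, pseudo = 4, trained = 100),
                              amplified_fraction = 0.35, seed = 11)
  pop2 <- generate_population(c(naive = 6, pseudo = 4, trained = 100),
                              amplified_fraction = 0.35, seed = 11)
  expect_identical(as.data.frame(pop1), as.data.frame(pop2))
  cells <- population_cells(pop1)
  expect_equal(sum(cells$amplified), 35)          # round(0.35 * 100)
  expect_true(all(cells$group[cells$amplified] == "trained"))
  expect_true(all(cells$n_events >= 80 & cells$n_events <= 300))
  # amplified_fraction = 0: groups exchangeable
  pop0 <- generate_population(c(naive = 8, trained = 8),
                              amplified_fraction = 0, seed = 12)
  expect_gt(ks_two_sample(pop0$amplitude_pA[pop0$group == "naive"],
                          pop0$amplitude_pA[pop0$group == "trained"])$p_value,
            1e-3)
  expect_error(generate_population(c(naive = 1, trained = 8)), "at least 2")
})

test_that("doubling the amplified subset reproduces pooled naive x2", {
  # mixing property behind the group-level reconstructions: on generated
  # cohorts the amplified cells' events are distributed as doubled naive
  # events
  hits <- 0L
  for (s in 1:100) {
    pop <- generate_population(c(naive = 8, trained = 8),
                               amplified_fraction = 1,
                               events_per_cell = c(80L, 120L),
                               seed = 100 + s)
    amp_ev <- pop$amplitude_pA[pop$group == "trained"]
    naive_ev <- pop$amplitude_pA[pop$group == "naive"]
    p <- cvm_two_sample(2 * naive_ev, amp_ev, n_perm = 199,
                        seed = s)$p_value
    if (p > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("waveform ensembles obey the binomial variance law", {
  # N = 1 binary channel: variance at a decay point = i^2 p(1-p) + sigma_b^2
  wf <- synth_nsfa_waveforms(n_channels = 1, unitary_current = 5,
                             baseline_sd = 0.1, n_events = 3000,
                             dt = 0.1, seed = 5)
  it <- which(wf$time > wf$onset + 2)[1]          # mid-decay sample
  p <- dualexp_shape(wf$time[it] - wf$onset, 0.5, 3)
  v_obs <- var(wf$current[it, ])
  v_exp <- 25 * p * (1 - p) + 0.01
  expect_lt(abs(v_obs - v_exp) / v_exp, 0.15)

  # clamped-open channels with zero baseline noise: zero variance at peak
  wf0 <- synth_nsfa_waveforms(n_channels = 10, baseline_sd = 0,
                              open_clamped = TRUE, n_events = 50, seed = 6)
  ipk <- which.max(rowMeans(wf0$current))
  expect_equal(var(wf0$current[ipk, ]), 0)
  # peak mean current never exceeds i * N
  expect_lte(max(rowMeans(wf0$current)), 10)
})

test_that("true rise-time annotation matches the analytic shape", {
  wf <- synth_nsfa_waveforms(rise = c(0.5, 2), decay = 4, n_events = 2,
                             dt = 0.05, seed = 7)
  ann <- apply_rise_time_filter_truth(wf, rise_limit = 1.5)
  # closed-form 10-90% rise of the dual-exponential, computed on a fine grid
  fine <- seq(0, 30, by = 0.002)
  expected_05 <- ampscale:::rise_1090_clean(dualexp_shape(fine, 0.5, 4), 0.002)
  expect_lt(abs(ann$rise_time_ms[1] - expected_05), 0.05)
  expect_true(ann$passes[1])
  expect_false(ann$passes[2])                     # slow event filtered out
  # every event slow: none pass
  wfslow <- synth_nsfa_waveforms(rise = 2, decay = 6, n_events = 5, seed = 8)
  expect_equal(sum(apply_rise_time_filter_truth(wfslow)$passes), 0)
})
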