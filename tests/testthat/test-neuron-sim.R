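test_that("passive cell settles to the leak reversal", {
  passive <- cell_model(g_na = 0, g_kdr = 0, g_ka = 0, g_km = 0,
                        g_cah = 0, g_kahp = 0)
  expect_lt(abs(resting_potential(passive) - passive$e_leak), 0.05)
  # full channel set shifts rest by at most a couple of millivolts
  expect_lt(abs(resting_potential(fixture_cell()) - (-80)), 3)
  expect_error(cell_model(g_na = -1), "non-negative")
})

test_that("spatial refinement leaves the resting potential unchanged", {
  v1 <- resting_potential(cell_model(max_seg = 10))
  v2 <- resting_potential(cell_model(max_seg = 5))
  expect_lt(abs(v1 - v2), 0.1)
})

test_that("step currents evoke regular spiking with adaptation", {
  cell <- fixture_cell()
  res <- simulate(cell, duration = 1200, i_inj = 0.6,
                  inj_window = c(200, 1200))
  sp <- res$spikes
  expect_gt(length(sp), 10)
  counts <- vapply(seq(200, 1000, by = 200), function(t0) {
    sum(sp >= t0 & sp < t0 + 200)
  }, numeric(1))
  # adaptation: later windows fire less than the first
  expect_lt(counts[5], counts[1])
  expect_gt(counts[5], 0)
  # removing the AHP conductance weakens adaptation
  noahp <- cell_model(g_kahp = 0)
  res2 <- simulate(noahp, duration = 1200, i_inj = 0.6,
                   inj_window = c(200, 1200))
  late2 <- sum(res2$spikes >= 1000)
  expect_gt(late2, counts[5])
})

test_that("no synaptic events and no injection means no spikes", {
  res <- simulate(fixture_cell(), duration = 500)
  expect_length(res$spikes, 0)
  expect_lt(diff(range(res$trace$v_soma[res$trace$time > 400])), 0.1)
})

test_that("temporal refinement converges", {
  cell <- fixture_cell()
  syn <- fixture_synapses()
  bg <- fixture_background()
  sch <- make_schedule(syn, e_hz = bg$e_hz, i_hz = bg$i_hz,
                       duration = 500, seed = 3)
  r1 <- simulate(cell, syn, sch, dt = 0.025)
  r2 <- simulate(cell, syn, sch, dt = 0.0125)
  expect_lte(abs(length(r1$spikes) - length(r2$spikes)), 1)
  o1 <- simulate(cell, syn, sch, dt = 0.025, na_off = TRUE)
  o2 <- simulate(cell, syn, sch, dt = 0.0125, na_off = TRUE)
  rms <- sqrt(mean((o1$trace$v_soma - o2$trace$v_soma)^2))
  expect_lt(rms, 0.2)
})

test_that("synapse calibration hits the target somatic amplitudes", {
  cell <- fixture_cell()
  syn <- fixture_synapses()
  expect_equal(sum(syn$kind == "E"), 350)
  expect_equal(sum(syn$kind == "I"), 350)
  expect_lt(abs(mean(syn$amp_pA[syn$kind == "E"]) - 70) / 70, 0.05)
  expect_lt(abs(mean(syn$amp_pA[syn$kind == "I"]) - 100) / 100, 0.05)
  # strong flag marks the tail of the generating mini distribution
  expect_true(all(syn$comp %in% cell$dend_idx))
  # a single average-amplitude excitatory synapse gives an EPSP of
  # order 1 mV
  s1 <- single_synapse(syn, which = which.min(abs(syn$amp_pA - 70) +
                                                (syn$kind == "I") * 1e6))
  sch <- manual_schedule(300, s1$syn_id, 420)
  r <- simulate(cell, s1, sch)
  epsp <- max(r$trace$v_soma) - r$trace$v_soma[r$trace$time == 299]
  expect_gt(epsp, 0.5)
  expect_lt(epsp, 3)
  # inhibitory conductances span the 0.9-2.7 nS range
  gi <- syn$g_peak_nS[syn$kind == "I"]
  expect_gt(min(gi), 0.7)
  expect_lt(max(gi), 3)
})

test_that("whole-cell amplification multiplies conductances only", {
  syn <- fixture_synapses()
  syn2 <- apply_whole_cell_amplification(syn, 2)
  expect_equal(syn2$g_peak_nS, 2 * syn$g_peak_nS)
  expect_equal(syn2$comp, syn$comp)
  expect_equal(unique(syn2$amplification), 2)
  expect_error(apply_whole_cell_amplification(syn, 0), "positive")
})

test_that("voltage-clamped currents scale exactly with the conductance factor", {
  cell <- fixture_cell()
  syn <- fixture_synapses()
  bg <- fixture_background()
  sch <- make_schedule(syn, e_hz = bg$e_hz, i_hz = bg$i_hz,
                       duration = 300, seed = 5)
  base <- simulate(cell, syn, sch, hold_v = -65, clamp = "space")
  for (k in c(0.5, 2, 3)) {
    amp <- simulate(cell, apply_whole_cell_amplification(syn, k), sch,
                    hold_v = -65, clamp = "space")
    expect_equal(amp$trace$i_net, k * base$trace$i_net, tolerance = 1e-12)
    # polarity preserved at every sample
    nz <- abs(base$trace$i_net) > 1e-12
    expect_true(all(sign(amp$trace$i_net[nz]) == sign(base$trace$i_net[nz])))
  }
  # holding at the excitatory reversal: no excitatory driving force
  r0 <- simulate(cell, syn, sch, hold_v = 0, clamp = "space")
  expect_lt(max(abs(r0$trace$i_excit)), 1e-12)
})

test_that("the net-current reversal is invariant under amplification", {
  cell <- fixture_cell()
  syn <- fixture_synapses()
  bg <- fixture_background()
  sch <- make_schedule(syn, e_hz = bg$e_hz, i_hz = bg$i_hz,
                       duration = 600, seed = 6)
  rev1 <- net_current_reversal(cell, syn, sch, window = 400)
  rev2 <- net_current_reversal(cell, apply_whole_cell_amplification(syn, 2),
                               sch, window = 400)
  expect_lt(abs(rev2 - rev1), 1)
  # scaling the clamped current scales its SD exactly
  r1 <- simulate(cell, syn, sch, hold_v = -60, clamp = "space")
  r2 <- simulate(cell, apply_whole_cell_amplification(syn, 2), sch,
                 hold_v = -60, clamp = "space")
  m1 <- net_current_metrics(r1, c(100, 600))
  m2 <- net_current_metrics(r2, c(100, 600))
  expect_equal(m2$i_sd / m1$i_sd, 2, tolerance = 1e-10)
})

test_that("simulated current fluctuations follow the shot-noise formula", {
  # near-instant rise makes the dual-exponential an exponential decay,
  # the shape the closed-form variance assumes
  cell <- fixture_cell()
  syn <- configure_synapses(cell, n_e = 350, n_i = 2,
                            e_kin = c(rise = 0.02, decay = 3), seed = 9)
  T_win <- 800
  sch <- make_schedule(syn, e_hz = 4, i_hz = 0, duration = 200 + T_win,
                       seed = 10)
  r <- simulate(cell, syn, sch, hold_v = -65, clamp = "space")
  m <- net_current_metrics(r, c(200, 200 + T_win), blank_spikes = FALSE)
  ev <- sch$events
  n_ev <- sum(ev$time >= 200 & ev$syn_id <= 350)
  # per-event somatic current amplitude at the holding potential
  amps <- syn$g_peak_nS[match(ev$syn_id[ev$time >= 200], syn$syn_id)] *
    1e-3 * 65
  v_pred <- shot_noise_variance(mean(amps), n_ev, 3, T_win,
                                cv = sd(amps) / mean(amps))
  expect_lt(abs(m$i_sd^2 - v_pred) / v_pred, 0.15)
})

test_that("schedules are deterministic and conserve modulated event counts", {
  syn <- fixture_synapses()
  s1 <- make_schedule(syn, e_hz = 3, i_hz = 2, duration = 1000, seed = 11)
  s2 <- make_schedule(syn, e_hz = 3, i_hz = 2, duration = 1000, seed = 11)
  expect_identical(s1$events, s2$events)
  # strong-fraction reallocation conserves the expected total E count
  lam <- 350 * 3
  n_e <- vapply(1:6, function(s) {
    sch <- make_schedule(syn, e_hz = 3, i_hz = 2, duration = 1000,
                         strong_fraction = 0.6, seed = 100 + s)
    sum(sch$events$syn_id %in% syn$syn_id[syn$kind == "E"])
  }, numeric(1))
  expect_lt(abs(mean(n_e) - lam), 3 * sqrt(lam / 6))
  # realised strong-event share approaches the target
  sch <- make_schedule(syn, e_hz = 3, i_hz = 2, duration = 5000,
                       strong_fraction = 0.6, seed = 12)
  e_ev <- sch$events$syn_id[sch$events$syn_id %in%
                              syn$syn_id[syn$kind == "E"]]
  strong_ids <- syn$syn_id[syn$kind == "E" & !is.na(syn$strong) &
                             syn$strong]
  share <- mean(e_ev %in% strong_ids)
  expect_lt(abs(share - 0.6), 0.03)
  expect_error(make_schedule(syn, e_hz = -1), "non-negative")
})

test_that("bump schedules modulate the excitatory rate with an alpha course", {
  syn <- fixture_synapses()
  sch <- make_schedule(syn, e_hz = 3, i_hz = 2, duration = 3300,
                       bump = list(tau = 24, factor = 5, n_bumps = 6),
                       t_start = 300, seed = 13)
  w <- bump_windows(sch)
  expect_equal(nrow(w), 6)
  expect_true(all(diff(as.vector(t(w[c("t_on", "t_off")]))) >= 0))
  # event density inside bump windows exceeds baseline
  e_ids <- syn$syn_id[syn$kind == "E"]
  ev <- sch$events[sch$events$syn_id %in% e_ids, ]
  in_bump <- rowSums(outer(ev$time, w$t_on, ">") &
                       outer(ev$time, w$t_off, "<")) > 0
  rate_in <- sum(in_bump) / sum(w$t_off - w$t_on)
  rate_out <- sum(!in_bump) / (3000 - sum(w$t_off - w$t_on))
  expect_gt(rate_in / rate_out, 1.5)
  # expected count conservation contract: lambda includes the alpha mass
  expect_error(make_schedule(syn, duration = 400,
                             bump = list(tau = 24, factor = 5,
                                         n_bumps = 6)),
               "overlap")
})

test_that("background rates place the net-current reversal near its target", {
  cell <- fixture_cell()
  syn <- fixture_synapses()
  bg <- fixture_background()
  revs <- vapply(1:4, function(s) {
    sch <- make_schedule(syn, e_hz = bg$e_hz, i_hz = bg$i_hz,
                         duration = 1300, seed = 20 + s)
    net_current_reversal(cell, syn, sch, window = 1000, settle = 100)
  }, numeric(1))
  expect_lt(abs(mean(revs) - (-37)), 3)
})

test_that("metric helpers behave on degenerate inputs", {
  cell <- fixture_cell()
  res <- simulate(cell, duration = 300)
  m <- net_current_metrics(res, c(100, 300))
  expect_equal(m$i_sd, 0)
  expect_error(net_current_metrics(res, c(400, 500)), "window")
  expect_error(voltage_metrics(res, c(100, 150)), "100 ms")
  expect_equal(spike_metrics(res)$count, 0)
  win <- tibble::tibble(t_on = c(0, 50), t_off = c(60, 120))
  expect_error(spike_metrics(res, win), "overlap")
  # io_slope identities
  s <- io_slope(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(s$slope, 2)
  expect_true(s$linear)
  flat <- io_slope(c(1, 2, 3), c(5, 5, 5))
  expect_equal(flat$slope, 0)
})
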