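#' Background rates that balance the net synaptic current
#'
#' Chooses per-synapse Poisson rates whose time-averaged excitatory and
#' inhibitory conductances place the reversal potential of the net
#' synaptic current at `target_reversal` (the value measured in vivo
#' during UP states and expected in the balanced regime).  The
#' time-averaged conductance of a synapse class is analytic -- peak
#' conductance times rate times the integral of the unit-peak
#' dual-exponential -- so the required inhibitory/excitatory rate ratio
#' follows in closed form from the conductance-weighted reversal.
#'
#' @param synapses A [configure_synapses()] set.
#' @param e_hz Excitatory per-synapse rate, Hz.
#' @param target_reversal Target reversal of the net synaptic current, mV.
#' @return A list with `e_hz`, `i_hz` and the conductance means per Hz.
#' @export
background_rates <- function(synapses, e_hz = 4.5, target_reversal = -37) {
  kin <- attr(synapses, "kinetics")
  rev <- attr(synapses, "reversals")
  if (target_reversal >= rev[["E"]] || target_reversal <= rev[["I"]]) {
    abort("`target_reversal` must lie between the synaptic reversals")
  }
  shape_int <- function(k) {
    tp <- log(k[["decay"]] / k[["rise"]]) * k[["rise"]] * k[["decay"]] /
      (k[["decay"]] - k[["rise"]])
    (k[["decay"]] - k[["rise"]]) / (exp(-tp / k[["decay"]]) -
                                      exp(-tp / k[["rise"]]))
  }
  gE_per_hz <- sum(synapses$g_peak_nS[synapses$kind == "E"]) *
    shape_int(kin$E) * 1e-3
  gI_per_hz <- sum(synapses$g_peak_nS[synapses$kind == "I"]) *
    shape_int(kin$I) * 1e-3
  need_ratio <- (rev[["E"]] - target_reversal) /
    (target_reversal - rev[["I"]])
  i_hz <- e_hz * need_ratio * gE_per_hz / gI_per_hz
  list(e_hz = e_hz, i_hz = i_hz, gE_per_hz = gE_per_hz,
       gI_per_hz = gI_per_hz)
}

# Latin-hypercube sample of the gain-protocol parameter space: the
# excitatory amplitude scale (x1-3, log scale -- it is a scale
# parameter) stretches the per-synapse AMPA conductance spread over
# ~0.6-10 nS while the inhibitory population stays at its default
# 0.9-2.7 nS spread; the excitatory rate spans 2-5 Hz.
sample_gain_space <- function(n_sets, seed) {
  lo <- c(e_scale = log(1), e_hz = 2)
  hi <- c(e_scale = log(3), e_hz = 5)
  pars <- with_seed_maybe(seed, lhs::randomLHS(n_sets, 2))
  pars <- sweep(sweep(pars, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(pars) <- names(lo)
  pars[, "e_scale"] <- exp(pars[, "e_scale"])
  pars
}

# Paired pre/post-amplification run on one schedule: identical event
# times, conductances multiplied by `factor` in the post run.
paired_runs <- function(cell, synapses, schedule, factor = 2, ...) {
  pre <- simulate(cell, synapses, schedule, ...)
  post <- simulate(cell, apply_whole_cell_amplification(synapses, factor),
                   schedule, ...)
  list(pre = pre, post = post)
}

#' Input-output gain protocol (paired conductance scaling)
#'
#' Latin-hypercube sample of the gain-protocol parameter space -- the
#' excitatory synaptic strength scaled x1-3 (stretching the per-synapse
#' AMPA peak-conductance spread over roughly 0.6-10 nS, with the
#' inhibitory population at its default 0.9-2.7 nS spread) and the
#' excitatory per-synapse rate 2-5 Hz, the inhibitory rate following
#' from the reversal-balance construction.  Per parameter set, paired
#' 500-ms runs at each strong-synapse activation fraction (15/30/45/60%)
#' before and after x2 whole-cell conductance scaling with identical
#' synaptic event times.  Net-current and voltage statistics are
#' measured in sodium-off companion runs (spike-free analog traces);
#' spike counts in the sodium-on runs.  Parameter sets whose sodium-off
#' pre-amplification mean somatic potential is -55 mV or above are
#' excluded (the depolarisation gate) and not simulated further.
#'
#' @param cell A [cell_model()].
#' @param n_sets Number of parameter sets sampled (the gate keeps a
#'   subset).
#' @param fractions Strong-synapse activation fractions.
#' @param duration Measurement window, ms.
#' @param t_equil Equilibration time before the window, ms.
#' @param n_trials Trials per (set, fraction) with fresh event times.
#' @param dt Integration step, ms.
#' @param seed Integer seed.
#' @return A list of class `gain_protocol`: `runs` (tibble per set x
#'   fraction x trial with currents, spikes and voltage statistics pre
#'   and post), `sets` (sampled parameters and the voltage gate),
#'   `per_set` (scaling ratios and input-output slopes per kept set) and
#'   `summary` (their averages).
#' @export
protocol_gain <- function(cell = cell_model(), n_sets = 10,
                          fractions = c(0.15, 0.30, 0.45, 0.60),
                          duration = 500, t_equil = 200, n_trials = 1,
                          dt = 0.025, seed = 1) {
  pars <- sample_gain_space(n_sets, seed)
  sets <- as_tibble(pars) |> dplyr::mutate(set = dplyr::row_number(),
                                           .before = 1)
  total <- t_equil + duration
  win <- c(t_equil, total)
  gate_v <- numeric(n_sets)
  i_rate <- numeric(n_sets)
  runs <- purrr::map_dfr(seq_len(n_sets), function(s) {
    syn <- configure_synapses(cell, e_target_pA = 70 * sets$e_scale[s],
                              seed = seed + 1000L + s)
    # inhibitory rate from the reversal-balance construction
    i_hz <- background_rates(syn, e_hz = sets$e_hz[s])$i_hz
    i_rate[s] <<- i_hz
    syn2 <- apply_whole_cell_amplification(syn, 2)
    one <- function(fi, tr, gate_check = FALSE) {
      sch <- make_schedule(syn, e_hz = sets$e_hz[s], i_hz = i_hz,
                           duration = total,
                           strong_fraction = fractions[fi],
                           seed = seed + 10000L + 100L * s + 10L * fi + tr)
      pre_off <- simulate(cell, syn, sch, dt = dt, na_off = TRUE)
      vm_pre <- voltage_metrics(pre_off, win)
      if (gate_check) {
        gate_v[s] <<- vm_pre$v_mean
        if (vm_pre$v_mean >= -55) return(NULL)
      }
      post_off <- simulate(cell, syn2, sch, dt = dt, na_off = TRUE)
      pre_on <- simulate(cell, syn, sch, dt = dt)
      post_on <- simulate(cell, syn2, sch, dt = dt)
      nm_pre <- net_current_metrics(pre_off, win)
      nm_post <- net_current_metrics(post_off, win)
      vm_post <- voltage_metrics(post_off, win)
      tibble(set = s, fraction = fractions[fi], trial = tr,
             i_mean_pre = nm_pre$i_mean, i_sd_pre = nm_pre$i_sd,
             i_mean_post = nm_post$i_mean, i_sd_post = nm_post$i_sd,
             spikes_pre = sum(pre_on$spikes >= win[1]),
             spikes_post = sum(post_on$spikes >= win[1]),
             v_mean_pre = vm_pre$v_mean, v_sd_pre = vm_pre$v_sd,
             v_mean_post = vm_post$v_mean, v_sd_post = vm_post$v_sd)
    }
    first <- one(1L, 1L, gate_check = TRUE)
    if (is.null(first)) return(NULL)
    rest <- purrr::map_dfr(seq_along(fractions), function(fi) {
      purrr::map_dfr(seq_len(n_trials), function(tr) {
        if (fi == 1L && tr == 1L) return(NULL)
        one(fi, tr)
      })
    })
    dplyr::bind_rows(first, rest)
  })
  sets$i_hz <- i_rate
  sets$v_first <- gate_v
  sets$v_gate <- gate_v < -55
  kept <- runs
  if (is.null(kept) || nrow(kept) == 0) {
    abort("all parameter sets excluded by the mean-voltage gate")
  }
  per_set <- kept |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      mean_ratio = mean(.data$i_mean_post / .data$i_mean_pre),
      sd_ratio = mean(.data$i_sd_post / .data$i_sd_pre),
      v_shift = mean(.data$v_mean_post - .data$v_mean_pre),
      v_sd_ratio = mean(.data$v_sd_post / .data$v_sd_pre),
      slope_pre = io_slope(.data$i_mean_pre, .data$spikes_pre)$slope,
      slope_post = io_slope(.data$i_mean_pre, .data$spikes_post)$slope,
      r_pre = io_slope(.data$i_mean_pre, .data$spikes_pre)$r,
      r_post = io_slope(.data$i_mean_pre, .data$spikes_post)$r,
      .groups = "drop") |>
    dplyr::mutate(slope_ratio = .data$slope_post / .data$slope_pre)
  summary <- tibble(
    mean_ratio = mean(per_set$mean_ratio),
    mean_ratio_sd = sd(per_set$mean_ratio),
    sd_ratio = mean(per_set$sd_ratio),
    sd_ratio_sd = sd(per_set$sd_ratio),
    v_shift = mean(per_set$v_shift),
    slope_ratio = mean(per_set$slope_ratio[is.finite(per_set$slope_ratio)],
                       na.rm = TRUE),
    n_sets_kept = nrow(per_set))
  structure(list(runs = runs, sets = sets, per_set = per_set,
                 summary = summary, seed = seed),
            class = "gain_protocol")
}

#' Net-current scaling across the excitation-inhibition balance
#'
#' Sweeps the inhibitory/excitatory rate balance (inhibitory rate falling
#' 11 to 3 Hz while the excitatory rate rises 2 to 10 Hz in 0.5-Hz steps,
#' 17 points), measuring at each point the 200-ms-averaged net synaptic
#' current under space clamp before and after x2 whole-cell scaling with
#' identical event times, plus the reversal potential of the net current
#' before and after (`n_rep` repeats per point).
#'
#' @param cell,dt As for [simulate()].
#' @param synapses Optional pre-built synapse set.
#' @param hold_v Holding potential for the current measurement, mV.
#' @param n_rep Repeats per rate point.
#' @param window Averaging window, ms.
#' @param reversal_grid Holding grid for the reversal scan.
#' @param seed Integer seed.
#' @return A tibble per rate point with mean `i_net` pre/post (nA), the
#'   rate ratio, reversal potentials pre/post and their difference.
#' @export
protocol_balance_sweep <- function(cell = cell_model(), synapses = NULL,
                           hold_v = -65, n_rep = 10, window = 200,
                           reversal_grid = c(-74, -68, -55, -40, -25, -10),
                           dt = 0.025, seed = 1) {
  syn <- synapses %||% configure_synapses(cell, seed = seed)
  i_rates <- seq(11, 3, by = -0.5)
  e_rates <- seq(2, 10, by = 0.5)
  settle <- 50
  dur <- settle + window
  purrr::map_dfr(seq_along(i_rates), function(k) {
    reps <- purrr::map_dfr(seq_len(n_rep), function(r) {
      sch <- make_schedule(syn, e_hz = e_rates[k], i_hz = i_rates[k],
                           duration = dur,
                           seed = seed + 100L * k + r)
      pre <- simulate(cell, syn, sch, dt = dt, hold_v = hold_v,
                      clamp = "space")
      post <- simulate(cell, apply_whole_cell_amplification(syn, 2), sch,
                       dt = dt, hold_v = hold_v, clamp = "space")
      tibble(
        i_net_pre = net_current_metrics(pre, c(settle, dur),
                                        blank_spikes = FALSE)$i_mean,
        i_net_post = net_current_metrics(post, c(settle, dur),
                                         blank_spikes = FALSE)$i_mean)
    })
    sch_rev <- make_schedule(syn, e_hz = e_rates[k], i_hz = i_rates[k],
                             duration = dur, seed = seed + 100L * k)
    rev_pre <- net_current_reversal(cell, syn, sch_rev,
                                    holding_grid = reversal_grid,
                                    window = window, settle = settle,
                                    dt = dt)
    rev_post <- net_current_reversal(
      cell, apply_whole_cell_amplification(syn, 2), sch_rev,
      holding_grid = reversal_grid, window = window, settle = settle,
      dt = dt)
    tibble(rate_ratio = i_rates[k] / e_rates[k],
           e_hz = e_rates[k], i_hz = i_rates[k],
           i_net_pre = mean(reps$i_net_pre),
           i_net_post = mean(reps$i_net_post),
           reversal_pre = rev_pre, reversal_post = rev_post,
           reversal_shift = rev_post - rev_pre)
  })
}

#' Bump-response protocols (instantaneous amplification)
#'
#' Across parameter sets sampled by Latin hypercube -- leak reversal
#' potential -100..-70 mV, excitatory and inhibitory synaptic strengths
#' independently scaled 0.6-2, background rates co-modulated up to x3 --
#' runs paired free simulations in which the excitatory rate is multiplied
#' by `1 + factor * alpha(t; tau)` at `n_bumps` random onsets, with
#' identical event times before and after x2 whole-cell conductance
#' scaling.  `protocol_bumps` (tau = 24 ms) reports per-bump spike-count
#' changes; `protocol_bump_probability` (tau = 12 ms) per-trace spike probabilities.
#'
#' @param cell Base cell (its leak reversal is overridden per set).
#' @param n_sets Number of parameter sets.
#' @param tau,factor Bump alpha time constant (ms) and rate multiplier.
#' @param n_bumps Bumps per trace.
#' @param slot_ms Trace time allotted per bump, ms.
#' @param base_e_hz Baseline excitatory rate before co-modulation, Hz.
#' @param dt Integration step, ms.
#' @param seed Integer seed.
#' @return For `protocol_bumps`: a list of class `bump_protocol_result` with
#'   `bumps` (per-bump counts pre/post), `sets`, and `summary` (fractions
#'   of bumps with increased / equal / decreased spike counts).  For
#'   `protocol_bump_probability`: a tibble per set with spike probabilities
#'   `p_before`, `p_after`.
#' @export
protocol_bumps <- function(cell = cell_model(), n_sets = 30, tau = 24,
                          factor = 5, n_bumps = 30, slot_ms = 160,
                          base_e_hz = 0.6, dt = 0.025, seed = 1) {
  res <- run_bump_sets(cell, n_sets, tau, factor, n_bumps, slot_ms,
                       base_e_hz, dt, seed)
  per_bump <- res$bumps
  summary <- tibble(
    frac_increased = mean(per_bump$count_post > per_bump$count_pre),
    frac_equal = mean(per_bump$count_post == per_bump$count_pre),
    frac_decreased = mean(per_bump$count_post < per_bump$count_pre),
    n_bumps = nrow(per_bump))
  structure(list(bumps = per_bump, sets = res$sets, summary = summary),
            class = "bump_protocol_result")
}

#' @rdname protocol_bumps
#' @export
protocol_bump_probability <- function(cell = cell_model(), n_sets = 35, tau = 12,
                           factor = 5, n_bumps = 30, slot_ms = 120,
                           base_e_hz = 0.6, dt = 0.025, seed = 1) {
  res <- run_bump_sets(cell, n_sets, tau, factor, n_bumps, slot_ms,
                       base_e_hz, dt, seed)
  res$bumps |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(p_before = mean(.data$count_pre > 0),
                     p_after = mean(.data$count_post > 0),
                     .groups = "drop") |>
    dplyr::left_join(res$sets, by = "set")
}

run_bump_sets <- function(cell, n_sets, tau, factor, n_bumps, slot_ms,
                          base_e_hz, dt, seed) {
  lo <- c(e_leak = -100, e_scale = 0.6, i_scale = 0.6, rate_mod = 1)
  hi <- c(e_leak = -70, e_scale = 2, i_scale = 2, rate_mod = 3)
  pars <- with_seed_maybe(seed, lhs::randomLHS(n_sets, 4))
  pars <- sweep(sweep(pars, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(pars) <- names(lo)
  sets <- as_tibble(pars) |> dplyr::mutate(set = dplyr::row_number(),
                                           .before = 1)
  t_equil <- 200
  duration <- t_equil + n_bumps * slot_ms
  bumps <- purrr::map_dfr(seq_len(n_sets), function(s) {
    cl <- cell
    cl$e_leak <- sets$e_leak[s]
    syn <- configure_synapses(cl, seed = seed + 2000L + s)
    syn$g_peak_nS <- syn$g_peak_nS *
      ifelse(syn$kind == "E", sets$e_scale[s], sets$i_scale[s])
    rates <- background_rates(syn, e_hz = base_e_hz)
    sch <- make_schedule(
      syn, e_hz = rates$e_hz * sets$rate_mod[s],
      i_hz = rates$i_hz * sets$rate_mod[s], duration = duration,
      bump = list(tau = tau, factor = factor, n_bumps = n_bumps),
      t_start = t_equil, seed = seed + 3000L + s)
    pp <- paired_runs(cl, syn, sch, factor = 2, dt = dt)
    wins <- bump_windows(sch)
    pre <- spike_metrics(pp$pre, wins)
    post <- spike_metrics(pp$post, wins)
    tibble(set = s, bump = pre$bump, count_pre = pre$count,
           count_post = post$count)
  })
  list(bumps = bumps, sets = sets)
}

#' Run a named protocol suite
#'
#' Dispatcher over the packaged protocol drivers: `"balance_sweep"`
#' (excitation-inhibition balance under clamp), `"gain"` (input-output
#' gain via strong-synapse fractions), `"gain_homogeneous"` (gain via
#' homogeneous rate increase), `"bumps"`/`"bump_probability"` (brief
#' elevated-activity transients) and `"mini_pipeline"` (miniature-event
#' analysis chain).
#'
#' @param name Protocol name.
#' @param ... Passed to the protocol function.
#' @return The protocol's result object.
#' @export
run_protocol <- function(name = c("balance_sweep", "gain",
                                  "gain_homogeneous", "bumps",
                                  "bump_probability", "mini_pipeline"),
                         ...) {
  switch(match.arg(name),
         balance_sweep = protocol_balance_sweep(...),
         gain = protocol_gain(...),
         gain_homogeneous = protocol_gain_homogeneous(...),
         bumps = protocol_bumps(...),
         bump_probability = protocol_bump_probability(...),
         mini_pipeline = run_mini_pipeline(...))
}

#' Gain protocol with homogeneous rate increase
#'
#' As [protocol_gain()] but the excitatory drive is raised by multiplying
#' the activation frequency of every excitatory synapse (rate multipliers
#' instead of strong-synapse reallocation), the comparison showing that
#' amplitude-side increases raise current fluctuations far more than
#' rate-side increases.
#'
#' @inheritParams protocol_gain
#' @param rate_levels Multipliers applied to the excitatory rate.
#' @return A `gain_protocol` (with `fraction` holding the rate level).
#' @export
protocol_gain_homogeneous <- function(cell = cell_model(), n_sets = 10,
                                      rate_levels = c(1, 4 / 3, 5 / 3, 2),
                                      duration = 500, t_equil = 200,
                                      dt = 0.025, seed = 1) {
  pars <- sample_gain_space(n_sets, seed)
  sets <- as_tibble(pars) |> dplyr::mutate(set = dplyr::row_number(),
                                           .before = 1)
  total <- t_equil + duration
  win <- c(t_equil, total)
  gate_v <- rep(NA_real_, n_sets)
  runs <- purrr::map_dfr(seq_len(n_sets), function(s) {
    syn <- configure_synapses(cell, e_target_pA = 70 * sets$e_scale[s],
                              seed = seed + 1000L + s)
    i_hz <- background_rates(syn, e_hz = sets$e_hz[s])$i_hz
    syn2 <- apply_whole_cell_amplification(syn, 2)
    out <- purrr::map_dfr(seq_along(rate_levels), function(fi) {
      sch <- make_schedule(syn, e_hz = sets$e_hz[s] * rate_levels[fi],
                           i_hz = i_hz, duration = total,
                           seed = seed + 10000L + 100L * s + fi)
      pre_off <- simulate(cell, syn, sch, dt = dt, na_off = TRUE)
      vm_pre <- voltage_metrics(pre_off, win)
      if (fi == 1L) {
        gate_v[s] <<- vm_pre$v_mean
      }
      if (!is.na(gate_v[s]) && gate_v[s] >= -55) return(NULL)
      post_off <- simulate(cell, syn2, sch, dt = dt, na_off = TRUE)
      pre_on <- simulate(cell, syn, sch, dt = dt)
      post_on <- simulate(cell, syn2, sch, dt = dt)
      nm_pre <- net_current_metrics(pre_off, win)
      nm_post <- net_current_metrics(post_off, win)
      tibble(set = s, fraction = rate_levels[fi], trial = 1L,
             i_mean_pre = nm_pre$i_mean, i_sd_pre = nm_pre$i_sd,
             i_mean_post = nm_post$i_mean, i_sd_post = nm_post$i_sd,
             spikes_pre = sum(pre_on$spikes >= win[1]),
             spikes_post = sum(post_on$spikes >= win[1]),
             v_mean_pre = vm_pre$v_mean, v_sd_pre = vm_pre$v_sd)
    })
    out
  })
  sets$v_first <- gate_v
  sets$v_gate <- !is.na(gate_v) & gate_v < -55
  if (is.null(runs) || nrow(runs) == 0) {
    abort("all parameter sets excluded by the mean-voltage gate")
  }
  per_set <- runs |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      mean_ratio = mean(.data$i_mean_post / .data$i_mean_pre),
      sd_ratio = mean(.data$i_sd_post / .data$i_sd_pre),
      slope_pre = io_slope(.data$i_mean_pre, .data$spikes_pre)$slope,
      slope_post = io_slope(.data$i_mean_pre, .data$spikes_post)$slope,
      .groups = "drop") |>
    dplyr::mutate(slope_ratio = .data$slope_post / .data$slope_pre)
  summary <- tibble(mean_ratio = mean(per_set$mean_ratio),
                    sd_ratio = mean(per_set$sd_ratio),
                    slope_ratio = mean(
                      per_set$slope_ratio[is.finite(per_set$slope_ratio)],
                      na.rm = TRUE),
                    n_sets_kept = nrow(per_set))
  structure(list(runs = runs, sets = sets, per_set = per_set,
                 summary = summary, seed = seed),
            class = "gain_protocol")
}

#' Simulate a blocker experiment on a synthetic population
#'
#' For every cell of a [generate_population()] cohort, builds the pre- and
#' post-blocker amplitude samples of a CaMKII-blocker experiment in which
#' the blocker divides the amplitude of a fraction `x` of the events of
#' amplified cells by `a`.  Two generative conventions are available
#' (unamplified cells always get i.i.d. base draws in both phases):
#'
#' * `"mixture-on-pre"` (default): an amplified cell's pre sample is a
#'   mixture in which a fraction `x` of events is `a`-fold amplified and
#'   its post sample is drawn from the base model.  Under this convention
#'   the fraction formula `x = (y - 1)/(a - 1)` and the multiplicative
#'   reversal are exact.
#' * `"fully-doubled-pre"`: the amplified cell's pre events are the
#'   population's (all amplified) events and the post sample has a
#'   fraction `x` divided back by `a` -- the biologically literal partial
#'   blocker, under which the formula is a (biased) approximation.
#'
#' @param population A `mini_population`.
#' @param x Fraction of events the blocker affects in amplified cells.
#' @param a Division factor of the blocker.
#' @param convention Generative convention (see above).
#' @param seed Optional integer seed.
#' @return A tibble with `cell_id`, `group`, `phase`, `amplitude_pA`
#'   (ground truth retained in attribute `"cells"`).
#' @export
simulate_blocker_experiment <- function(population, x = 0.65, a = 2,
                                        convention = c("mixture-on-pre",
                                                       "fully-doubled-pre"),
                                        seed = NULL) {
  cells <- population_cells(population)
  model <- attr(population, "model")
  convention <- match.arg(convention)
  assert_scalar_number(x, "x", 0, 1)
  with_seed_maybe(seed, {
    phases <- purrr::pmap_dfr(
      cells[c("cell_id", "group", "n_events", "amplified")],
      function(cell_id, group, n_events, amplified) {
        pop_pre <- population$amplitude_pA[population$cell_id == cell_id]
        if (!amplified) {
          pre <- pop_pre
          post <- draw_base_amplitudes(model, n_events)
        } else if (convention == "mixture-on-pre") {
          base_pre <- draw_base_amplitudes(model, n_events)
          hit <- runif(n_events) < x
          pre <- ifelse(hit, a * base_pre, base_pre)
          post <- draw_base_amplitudes(model, n_events)
        } else {
          pre <- pop_pre
          base_post <- a * draw_base_amplitudes(model, n_events)
          hit <- runif(n_events) < x
          post <- ifelse(hit, base_post / a, base_post)
        }
        tibble(cell_id = cell_id, group = group,
               phase = rep(c("pre", "post"),
                           c(length(pre), length(post))),
               amplitude_pA = c(pre, post))
      })
    attr(phases, "cells") <- cells
    attr(phases, "true_x") <- x
    attr(phases, "true_a") <- a
    attr(phases, "convention") <- convention
    phases
  })
}

#' Full miniature-event analysis pipeline
#'
#' Runs the complete analysis chain on a pre/post blocker event table:
#' per-cell blocker effects, two-cluster segregation, affected-fraction
#' estimation from the affected-cluster mean effect, per-cell reversal of
#' the blocker effect under the multiplicative, additive and triple
#' models, reconstruction of the affected cluster by doubling all control
#' events, and the cumulative-curve reconstruction from control cell
#' means.
#'
#' @param events A tibble with `cell_id`, `group`, `phase`,
#'   `amplitude_pA` (e.g. from [simulate_blocker_experiment()]).
#' @param a Assumed per-event division factor of the blocker.
#' @param control_group Group used for the doubling reconstructions.
#' @param n_perm Permutations for the Cramer-von Mises tests.
#' @param reconstruction_fraction Fraction of control cell means doubled
#'   in the cumulative-curve reconstruction (defaults to the affected
#'   share among non-control cells).
#' @param seed Integer seed.
#' @return A list of class `mini_pipeline` with elements `effects`,
#'   `clusters`, `affected` (summary incl. the estimated fraction),
#'   `reversals` (per cell x model), `doubling` (CvM of 2 x control vs
#'   affected pre), `cumulative` (KS of reconstructed vs observed cell
#'   means).
#' @export
run_mini_pipeline <- function(events, a = 2, control_group = "naive",
                              n_perm = 999,
                              reconstruction_fraction = NULL, seed = 1) {
  stopifnot(all(c("cell_id", "group", "phase", "amplitude_pA") %in%
                  names(events)))
  effects <- blocker_effects(events)
  groups <- events |>
    dplyr::distinct(.data$cell_id, .data$group)
  effects <- dplyr::left_join(effects, groups, by = "cell_id")
  clusters <- NULL
  if (nrow(effects) >= 4) {
    clusters <- cluster_effects(effects, seed = seed)
  } else {
    warn("fewer than 4 cells: clustering skipped")
  }
  affected_ids <- if (!is.null(clusters) && !clusters$degenerate) {
    clusters$labels$cell_id[clusters$labels$cluster == "affected"]
  } else {
    character(0)
  }
  aff_eff <- effects[effects$cell_id %in% affected_ids, ]
  affected <- dplyr::bind_cols(
    tibble(n_affected = length(affected_ids),
           mean_y = mean(aff_eff$y_mean)),
    affected_fraction(mean(aff_eff$y_mean), a))
  reversals <- purrr::map_dfr(affected_ids, function(cid) {
    d <- events[events$cell_id == cid, ]
    pre <- d$amplitude_pA[d$phase == "pre"]
    post <- d$amplitude_pA[d$phase == "post"]
    purrr::map_dfr(c("multiplicative", "additive", "triple"), function(mt) {
      dplyr::bind_cols(
        tibble(cell_id = cid),
        tidy(reverse_blocker(pre, post, model_tag = mt, a = a,
                             n_perm = n_perm, seed = seed)))
    })
  })
  ctrl_pre <- events[events$group == control_group & events$phase == "pre", ]
  aff_pre <- events[events$cell_id %in% affected_ids &
                      events$phase == "pre", ]
  doubling <- NULL
  if (nrow(aff_pre) > 5 && nrow(ctrl_pre) > 5) {
    doubling <- naive_doubling_reconstruction(ctrl_pre$amplitude_pA,
                                              aff_pre$amplitude_pA,
                                              n_perm = n_perm, seed = seed)
  }
  cell_means <- events[events$phase == "pre", ] |>
    dplyr::group_by(.data$cell_id, .data$group) |>
    dplyr::summarise(cell_mean = mean(.data$amplitude_pA),
                     .groups = "drop")
  ctrl_means <- cell_means$cell_mean[cell_means$group == control_group]
  other_means <- cell_means$cell_mean[cell_means$group != control_group]
  frac <- reconstruction_fraction %||% {
    other_ids <- cell_means$cell_id[cell_means$group != control_group]
    if (length(other_ids)) mean(other_ids %in% affected_ids) else 0.35
  }
  cumulative <- NULL
  if (length(ctrl_means) >= 5 && length(other_means) >= 5) {
    cumulative <- reconstruct_group_curve(ctrl_means, fraction = frac,
                                          factor = a,
                                          target_cell_means = other_means,
                                          n_boot = 100, seed = seed)
  }
  structure(list(effects = effects, clusters = clusters,
                 affected = affected, reversals = reversals,
                 doubling = doubling, cumulative = cumulative),
            class = "mini_pipeline")
}

#' @export
print.mini_pipeline <- function(x, ...) {
  cat(sprintf(
    "<mini_pipeline> %d cells; affected cluster: %d cells, mean effect %.3g, estimated affected fraction %.3g\n",
    nrow(x$effects), x$affected$n_affected, x$affected$mean_y,
    x$affected$x))
  invisible(x)
}
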