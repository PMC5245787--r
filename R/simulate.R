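#' Run the conductance-based simulation
#'
#' Integrates the cable, channel and synapse equations with the compiled
#' backward-Euler core and returns the somatic voltage, the total
#' excitatory, inhibitory and net synaptic currents, the calcium
#' concentration and the detected spike times.  The net synaptic current
#' is reported in the depolarising-positive convention
#' `I_net = -(I_E + I_I)` so that net excitation is positive.
#'
#' @param cell A [cell_model()].
#' @param synapses A [configure_synapses()] set (or `NULL` for none).
#' @param schedule An [make_schedule()] result (or `NULL`).
#' @param duration Simulation length, ms (defaults to the schedule's).
#' @param dt Integration step, ms (<= 0.05 recommended).
#' @param record_dt Sampling interval of the recorded traces, ms.
#' @param hold_v Holding potential for voltage clamp, mV, or `NULL`.
#' @param clamp Clamp geometry: `"space"` fixes every compartment at
#'   `hold_v` (ideal clamp: synaptic currents are then exactly linear in
#'   the conductances), `"soma"` clamps only the somatic compartments.
#' @param na_off Set the sodium conductance to zero (subthreshold
#'   recordings without spikes).
#' @param v_init Initial potential, mV (defaults to `e_leak`).
#' @param i_inj Step current injection at the soma, nA.
#' @param inj_window `c(start, end)` of the injection, ms.
#' @param spike_thresh Spike detection threshold (upward crossing), mV.
#' @param refractory Spike deduplication interval, ms.
#' @return An object of class `sim_result`: `trace` (tibble `time`,
#'   `v_soma`, `i_excit`, `i_inhib`, `i_net`, `ca`, and `i_clamp` under a
#'   somatic clamp), `spikes` (ms), and the call metadata.
#' @export
simulate <- function(cell, synapses = NULL, schedule = NULL,
                     duration = NULL, dt = 0.025, record_dt = 0.1,
                     hold_v = NULL, clamp = c("space", "soma"),
                     na_off = FALSE, v_init = NULL, i_inj = 0,
                     inj_window = c(0, Inf), spike_thresh = -10,
                     refractory = 2) {
  stopifnot(inherits(cell, "cell_model"))
  if (dt <= 0 || dt > 0.05) abort("`dt` must be in (0, 0.05] ms")
  duration <- duration %||% schedule$duration %||%
    abort("`duration` is needed when no schedule is given")
  if (is.null(synapses)) {
    syn <- list(comp = integer(0), type = integer(0),
                g_peak_uS = numeric(0), tau_rise = c(0.5, 1),
                tau_decay = c(3, 8), e_rev = c(0, -75))
    ev <- list(time = numeric(0), syn = integer(0))
  } else {
    syn <- syn_core_list(synapses)
    if (is.null(schedule)) {
      ev <- list(time = numeric(0), syn = integer(0))
    } else {
      idx <- match(schedule$events$syn_id, synapses$syn_id)
      keep <- !is.na(idx) & is.finite(schedule$events$time)
      ev <- list(time = schedule$events$time[keep],
                 syn = as.integer(idx[keep] - 1L))
    }
  }
  clamp_mode <- 0L
  if (!is.null(hold_v)) {
    clamp_mode <- switch(match.arg(clamp), space = 1L, soma = 2L)
  }
  ctrl <- sim_ctrl(duration = duration, dt = dt,
                   rec_every = max(1L, round(record_dt / dt)),
                   v_init = v_init %||% cell$e_leak,
                   clamp_mode = clamp_mode,
                   v_hold = hold_v %||% 0,
                   na_off = na_off, passive_only = FALSE,
                   soma_idx = as.integer(cell$soma_idx - 1L),
                   i_inj = i_inj, inj_start = inj_window[1],
                   inj_end = min(inj_window[2], duration + 1),
                   spike_thresh = spike_thresh, refractory = refractory)
  res <- .sim_core(cell_core_list(cell), syn, ev, ctrl)
  if (clamp_mode == 0L &&
      any(!is.finite(res$v_soma)) || isTRUE(max(res$v_soma) > 100)) {
    abort("integration diverged: reduce `dt` or check parameters")
  }
  trace <- tibble(time = res$time, v_soma = res$v_soma,
                  i_excit = res$i_excit, i_inhib = res$i_inhib,
                  i_net = -(res$i_excit + res$i_inhib), ca = res$ca)
  if (clamp_mode == 2L) trace$i_clamp <- res$i_clamp
  structure(list(trace = trace, spikes = res$spikes, dt = dt,
                 duration = duration, clamp_mode = clamp_mode,
                 hold_v = hold_v, na_off = na_off,
                 schedule = schedule),
            class = "sim_result")
}

# Control list for the compiled core, with defaults.
sim_ctrl <- function(duration, dt, rec_every = 4L, v_init = -80,
                     clamp_mode = 0L, v_hold = 0, na_off = FALSE,
                     passive_only = FALSE, soma_idx = integer(0),
                     i_inj = 0, inj_start = 0, inj_end = 0,
                     spike_thresh = -10, refractory = 2) {
  list(duration = duration, dt = dt, rec_every = as.integer(rec_every),
       v_init = v_init, clamp_mode = as.integer(clamp_mode),
       v_hold = v_hold, na_off = na_off, passive_only = passive_only,
       soma_idx = soma_idx, i_inj = i_inj, inj_start = inj_start,
       inj_end = inj_end, spike_thresh = spike_thresh,
       refractory = refractory)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %.5g ms, %d spikes%s; somatic V in [%.3g, %.3g] mV\n",
    x$duration, length(x$spikes),
    if (x$clamp_mode > 0) sprintf(" (clamped at %.3g mV)", x$hold_v) else "",
    min(x$trace$v_soma), max(x$trace$v_soma)))
  invisible(x)
}

# Rows of a trace inside a window, optionally excluding +-blank_ms around
# each spike.
window_rows <- function(result, window, blank_spikes = TRUE, blank_ms = 2) {
  tr <- result$trace
  keep <- tr$time >= window[1] & tr$time <= window[2]
  if (!any(keep)) abort("empty analysis window")
  if (blank_spikes && length(result$spikes)) {
    for (ts in result$spikes) {
      keep <- keep & !(tr$time >= ts - blank_ms & tr$time <= ts + blank_ms)
    }
  }
  keep
}

#' Mean and SD of the net synaptic current
#'
#' Time-average and SD of `I_net` over a window, with samples within
#' `blank_ms` of a spike excluded (capacitive and action-current
#' contamination) unless the run was spike-free.
#'
#' @param result A [simulate()] result.
#' @param window `c(start, end)`, ms.
#' @param blank_spikes,blank_ms Spike-blanking control.
#' @return A one-row tibble with `i_mean`, `i_sd` (nA) and `n_samples`.
#' @export
net_current_metrics <- function(result, window = NULL, blank_spikes = TRUE,
                                blank_ms = 2) {
  window <- window %||% c(0, result$duration)
  keep <- window_rows(result, window, blank_spikes, blank_ms)
  x <- result$trace$i_net[keep]
  tibble(i_mean = mean(x), i_sd = sd(x), n_samples = sum(keep))
}

#' Membrane-potential statistics
#'
#' Mean and SD of the somatic potential over a window (with spike
#' blanking), plus the r^2 of a Gaussian fit to the voltage histogram --
#' the balanced-state prediction is a normal voltage distribution.
#'
#' @inheritParams net_current_metrics
#' @param n_bins Histogram bins for the Gaussian fit.
#' @return A one-row tibble with `v_mean`, `v_sd` (mV) and `normal_r2`.
#' @export
voltage_metrics <- function(result, window = NULL, blank_spikes = TRUE,
                            blank_ms = 2, n_bins = 30) {
  window <- window %||% c(0, result$duration)
  if (diff(window) < 100) abort("window shorter than 100 ms")
  keep <- window_rows(result, window, blank_spikes, blank_ms)
  v <- result$trace$v_soma[keep]
  h <- graphics::hist(v, breaks = n_bins, plot = FALSE)
  pred <- dnorm(h$mids, mean(v), sd(v))
  r2 <- suppressWarnings(cor(h$density, pred)^2)
  tibble(v_mean = mean(v), v_sd = sd(v), normal_r2 = r2)
}

#' Spike counts and per-bump spike statistics
#'
#' @param result A [simulate()] result.
#' @param windows Optional tibble of windows (`t_on`, `t_off`), e.g. from
#'   [bump_windows()]; overlapping windows are rejected.
#' @return With `windows = NULL`, a one-row tibble with the total spike
#'   `count`.  Otherwise one row per window with `count`, `any_spike`,
#'   plus the overall `probability` (fraction of windows with >= 1 spike)
#'   as an attribute.
#' @export
spike_metrics <- function(result, windows = NULL) {
  if (is.null(windows)) {
    return(tibble(count = length(result$spikes)))
  }
  stopifnot(all(c("t_on", "t_off") %in% names(windows)))
  w <- windows[order(windows$t_on), ]
  if (any(diff(as.vector(rbind(w$t_on, w$t_off))) < 0)) {
    abort("bump windows overlap")
  }
  out <- dplyr::mutate(
    w,
    count = vapply(seq_len(nrow(w)), function(i) {
      sum(result$spikes >= w$t_on[i] & result$spikes < w$t_off[i])
    }, numeric(1)),
    any_spike = .data$count > 0)
  attr(out, "probability") <- mean(out$any_spike)
  out
}

#' Reversal potential of the net synaptic current
#'
#' Clamps the cell at each holding potential of `holding_grid`, averages
#' the net synaptic current over `window` ms of background activity and
#' interpolates the potential at which the average crosses zero.
#'
#' @param cell,synapses,schedule As for [simulate()].
#' @param holding_grid Holding potentials, mV (must bracket the zero
#'   crossing).
#' @param window Averaging window length, ms.
#' @param settle Time allowed before the averaging window, ms.
#' @param dt Integration step, ms.
#' @return Reversal potential, mV.
#' @export
net_current_reversal <- function(cell, synapses, schedule,
                                 holding_grid = seq(-70, -10, by = 10),
                                 window = 200, settle = 50, dt = 0.025) {
  dur <- settle + window
  imean <- vapply(holding_grid, function(vh) {
    res <- simulate(cell, synapses, schedule, duration = dur, dt = dt,
                    hold_v = vh, clamp = "space")
    net_current_metrics(res, c(settle, dur), blank_spikes = FALSE)$i_mean
  }, numeric(1))
  sgn <- sign(imean)
  flips <- which(diff(sgn) != 0)
  if (!length(flips)) abort("no sign change of I_net on the holding grid")
  k <- flips[1]
  stats::approx(imean[k:(k + 1)], holding_grid[k:(k + 1)], xout = 0)$y
}

#' Input-output curve and its slope
#'
#' Least-squares line through (mean net synaptic current, spike count)
#' pairs; the regime is flagged non-linear when `|r| <= r_gate`.
#'
#' @param i_mean Mean net synaptic current per condition (nA,
#'   depolarising-positive).
#' @param spikes Spike counts per condition.
#' @param r_gate Linearity gate on the correlation coefficient.
#' @return A one-row tibble with `slope`, `intercept`, `r`, `linear`.
#' @export
io_slope <- function(i_mean, spikes, r_gate = 0.95) {
  stopifnot(length(i_mean) == length(spikes), length(i_mean) >= 3)
  if (sd(spikes) == 0) {
    return(tibble(slope = 0, intercept = mean(spikes), r = NA_real_,
                  linear = FALSE))
  }
  fit <- lm(spikes ~ i_mean)
  r <- cor(i_mean, spikes)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = r, linear = abs(r) > r_gate)
}
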