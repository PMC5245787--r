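#' Dual-exponential synaptic event shape
#'
#' Difference-of-exponentials time course normalised to unit peak, the
#' conventional "alpha-like" shape of a fast synaptic conductance or of the
#' open probability of a receptor population: rising with time constant
#' `rise` and decaying with `decay`.
#'
#' @param t Time from event onset, ms (values < 0 give 0).
#' @param rise,decay Rise and decay time constants, ms (`decay > rise`).
#' @return Shape values with peak exactly 1.
#' @export
dualexp_shape <- function(t, rise, decay) {
  stopifnot(decay > rise, rise > 0)
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  norm <- exp(-tp / decay) - exp(-tp / rise)
  out <- ifelse(t > 0, (exp(-t / decay) - exp(-t / rise)) / norm, 0)
  pmin(out, 1)
}

# 10-90% rise time of a clean (noiseless) waveform sampled at dt, by linear
# interpolation of the crossings of 10% and 90% of peak on the rising limb.
# Returns NA for flat traces.
rise_1090_clean <- function(y, dt) {
  pk <- max(y)
  if (!is.finite(pk) || pk <= 0 || diff(range(y)) == 0) return(NA_real_)
  ip <- which.max(y)
  cross <- function(level) {
    idx <- which(y[seq_len(ip)] >= level)[1]
    if (is.na(idx)) return(NA_real_)
    if (idx == 1L) return(0)
    # linear interpolation between idx-1 and idx
    y0 <- y[idx - 1L]; y1 <- y[idx]
    ((idx - 2L) + (level - y0) / (y1 - y0)) * dt
  }
  t10 <- cross(0.1 * pk)
  t90 <- cross(0.9 * pk)
  t90 - t10
}

#' Measured 10-90% rise time of a possibly noisy trace
#'
#' The trace is baseline-subtracted (mean of the first `baseline_n`
#' samples), lightly smoothed with a 3-point moving average, and the 10-90%
#' rise time of the rising limb to the peak is interpolated linearly.
#'
#' @param y Current trace (one event), pA.
#' @param dt Sample interval, ms.
#' @param baseline_n Number of leading samples treated as baseline.
#' @return Rise time in ms, or `NA` for flat traces.
#' @export
rise_time_1090 <- function(y, dt, baseline_n = max(1L, floor(0.05 * length(y)))) {
  y <- y - mean(y[seq_len(baseline_n)])
  n <- length(y)
  ys <- y
  if (n >= 3) {
    ys <- (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
  }
  rise_1090_clean(ys, dt)
}

#' Simulate miniature-event waveform ensembles for NSFA
#'
#' Generates per-event current traces as the sum of `n_channels`
#' independent binary channels, each open at time `t` with probability
#' given by a dual-exponential time course that reaches 1 at the peak, plus
#' Gaussian baseline noise.  At the ensemble peak all channels are open on
#' average, so the ensemble variance about the mean current `I(t)` during
#' the decay follows the single-channel parabola
#' `sigma^2(t) = i * I(t) - I(t)^2 / N + sigma_b^2`, the relation inverted
#' by peak-scaled non-stationary fluctuation analysis.
#'
#' @param n_channels Number of channels `N` (>= 1) per event.
#' @param unitary_current Single-channel current `i`, pA (> 0).
#' @param rise,decay Open-probability rise/decay time constants, ms.  Both
#'   may be vectors of length `n_events` to mix kinetic classes.
#' @param baseline_sd Gaussian baseline noise SD, pA.
#' @param dt Sample interval, ms (> 0).
#' @param n_events Number of events.
#' @param t_baseline Pre-event baseline window, ms.
#' @param t_total Total trace duration, ms.
#' @param open_clamped If `TRUE` all channels are deterministically open
#'   with probability-course rounded to {0,1} at the peak sample
#'   (diagnostic: no channel noise at the peak).
#' @param seed Optional integer seed.
#' @return An object of class `nsfa_waveforms`: a list with `time` (ms),
#'   `current` (matrix, time x events, pA), the generating parameters, and
#'   per-event true 10-90% rise times.
#' @export
synth_nsfa_waveforms <- function(n_channels = 20, unitary_current = 1,
                                 rise = 0.5, decay = 3, baseline_sd = 0.2,
                                 dt = 0.1, n_events = 300, t_baseline = 10,
                                 t_total = 40, open_clamped = FALSE,
                                 seed = NULL) {
  if (n_channels < 1) abort("`n_channels` must be >= 1")
  assert_scalar_number(unitary_current, "unitary_current", lower = 1e-12)
  if (dt <= 0) abort("`dt` must be positive")
  rise <- rep_len(rise, n_events)
  decay <- rep_len(decay, n_events)
  time <- seq(0, t_total, by = dt)
  onset <- t_baseline
  with_seed_maybe(seed, {
    cur <- matrix(0, nrow = length(time), ncol = n_events)
    rise_true <- numeric(n_events)
    tfine <- seq(0, t_total - onset, by = min(dt, 0.01))
    for (j in seq_len(n_events)) {
      p <- dualexp_shape(time - onset, rise[j], decay[j])
      if (open_clamped) {
        k <- n_channels * round(p)
      } else {
        k <- rbinom(length(p), n_channels, p)
      }
      cur[, j] <- unitary_current * k +
        rnorm(length(p), sd = baseline_sd)
      rise_true[j] <- rise_1090_clean(
        dualexp_shape(tfine, rise[j], decay[j]), min(dt, 0.01))
    }
    structure(
      list(time = time, current = cur, dt = dt, onset = onset,
           n_channels = n_channels, unitary_current = unitary_current,
           rise = rise, decay = decay, baseline_sd = baseline_sd,
           rise_time_true = rise_true),
      class = "nsfa_waveforms")
  })
}

#' @export
print.nsfa_waveforms <- function(x, ...) {
  cat(sprintf(
    "<nsfa_waveforms> %d events x %d samples (dt %.3g ms); N = %d, i = %.3g pA, baseline SD %.3g pA\n",
    ncol(x$current), nrow(x$current), x$dt, x$n_channels,
    x$unitary_current, x$baseline_sd))
  invisible(x)
}

#' @export
as_tibble.nsfa_waveforms <- function(x, ...) {
  tibble(
    time_ms = rep(x$time, times = ncol(x$current)),
    event = rep(seq_len(ncol(x$current)), each = nrow(x$current)),
    current_pA = as.vector(x$current))
}

#' Annotate waveforms with their true 10-90% rise times
#'
#' Attaches to each event the analytic 10-90% rise time of its noiseless
#' open-probability time course and flags which events pass a rise-time
#' acceptance limit.  Flat traces get an `NA` rise time.
#'
#' @param wf An [synth_nsfa_waveforms()] set.
#' @param rise_limit Acceptance limit, ms.
#' @return A tibble with columns `event`, `rise_time_ms`, `passes`.
#' @export
apply_rise_time_filter_truth <- function(wf, rise_limit = 1.5) {
  stopifnot(inherits(wf, "nsfa_waveforms"))
  tibble(event = seq_along(wf$rise_time_true),
         rise_time_ms = wf$rise_time_true,
         passes = !is.na(wf$rise_time_true) & wf$rise_time_true < rise_limit)
}
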