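#' Poisson activation schedule
#'
#' Draws independent Poisson event trains for every synapse.  Two
#' modulations of the excitatory drive are supported:
#'
#' * `strong_fraction`: the expected share of excitatory events carried by
#'   the strong synapses is set to this value by raising the strong-synapse
#'   rate and lowering the weak-synapse rate, while conserving the total
#'   expected number of excitatory events (`n_E * e_hz * duration`) -- the
#'   signature of a cell recruited into an active Hebbian memory pattern.
#' * `bump`: the instantaneous excitatory rate is multiplied by
#'   `1 + factor * alpha((t - onset)/tau)` with the classical alpha
#'   function `alpha(u) = u exp(-u)` (peak `1/e` at `u = 1`), at
#'   `n_bumps` onsets placed randomly, one per equal division of the
#'   trace, with non-overlapping windows `[onset, onset + window]`
#'   (default `4 * tau`).
#'
#' @param synapses A [configure_synapses()] set.
#' @param e_hz,i_hz Baseline per-synapse Poisson rates, Hz.
#' @param duration Schedule length, ms.
#' @param strong_fraction Optional target share (0-1) of excitatory events
#'   from strong synapses.
#' @param bump Optional list `list(tau =, factor =, n_bumps =, window =)`
#'   (ms, unitless, count, ms).
#' @param t_start Events are only generated from this time on (lets the
#'   membrane equilibrate first), ms.
#' @param seed Optional integer seed; identical seeds give identical event
#'   times, the contract that makes paired pre/post-amplification runs
#'   within-realisation comparisons.
#' @return A list of class `activation_schedule`: `events` (tibble `time`,
#'   `syn_id`, sorted), `duration`, `rates`, `bump` (with realised
#'   `onsets` and `windows`), `strong_fraction`.
#' @export
make_schedule <- function(synapses, e_hz = 4, i_hz = 2, duration = 1000,
                          strong_fraction = NULL, bump = NULL,
                          t_start = 0, seed = NULL) {
  stopifnot(inherits(synapses, "synapse_set"))
  if (e_hz < 0 || i_hz < 0) abort("rates must be non-negative")
  is_e <- synapses$kind == "E"
  n_e <- sum(is_e); n_i <- sum(!is_e)
  rate <- ifelse(is_e, e_hz, i_hz) / 1000           # per ms
  if (!is.null(strong_fraction)) {
    assert_scalar_number(strong_fraction, "strong_fraction", 0, 1)
    strong <- is_e & !is.na(synapses$strong) & synapses$strong
    weak <- is_e & !strong
    if (sum(strong) == 0 || sum(weak) == 0) {
      abort("need both strong and weak excitatory synapses")
    }
    total <- n_e * e_hz / 1000
    rate[strong] <- strong_fraction * total / sum(strong)
    rate[weak] <- (1 - strong_fraction) * total / sum(weak)
  }
  gen_span <- duration - t_start
  with_seed_maybe(seed, {
    onsets <- numeric(0); window <- NULL
    if (!is.null(bump)) {
      bump$window <- bump$window %||% (4 * bump$tau)
      slots <- seq(t_start, duration, length.out = bump$n_bumps + 1)
      slot_len <- diff(slots)[1]
      if (slot_len < bump$window) {
        abort("bump windows overlap: shorten the window or the bump count")
      }
      onsets <- slots[-length(slots)] +
        runif(bump$n_bumps, 0, slot_len - bump$window)
    }
    # factor by which the bumps multiply the expected event count of an
    # excitatory synapse over the whole trace (the alpha function
    # integrates to tau)
    alpha_int <- if (is.null(bump)) 0 else
      bump$factor * bump$tau * length(onsets)
    lam <- rate * gen_span
    modulated <- is_e & !is.null(bump)
    lam[modulated] <- lam[modulated] * (1 + alpha_int / gen_span)
    counts <- rpois(length(lam), lam)
    syn_of_ev <- rep(synapses$syn_id, counts)
    mod_of_ev <- rep(modulated, counts)
    times <- numeric(length(syn_of_ev))
    times[!mod_of_ev] <- runif(sum(!mod_of_ev), 0, gen_span)
    if (any(mod_of_ev)) {
      times[mod_of_ev] <- sample_modulated_times(
        sum(mod_of_ev), gen_span, bump, onsets - t_start)
    }
    ev <- tibble(time = t_start + times, syn_id = syn_of_ev)
    ev <- ev[order(ev$time), ]
    structure(list(events = ev, duration = duration,
                   rates = c(e_hz = e_hz, i_hz = i_hz),
                   strong_fraction = strong_fraction,
                   bump = if (is.null(bump)) NULL else
                     c(bump, list(onsets = onsets))),
              class = "activation_schedule")
  })
}

# Draw k event times from the bump-modulated intensity by inverse-CDF
# sampling on a fine grid (the conditional-times representation of an
# inhomogeneous Poisson process given its count).
sample_modulated_times <- function(k, span, bump, onsets) {
  grid <- seq(0, span, by = min(1, bump$tau / 8))
  lam <- rep(1, length(grid))
  for (on in onsets) {
    u <- (grid - on) / bump$tau
    lam <- lam + ifelse(u > 0, bump$factor * u * exp(-u), 0)
  }
  cdf <- cumsum(lam)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(cdf, grid, xout = runif(k), ties = "ordered")$y
}

#' @export
print.activation_schedule <- function(x, ...) {
  cat(sprintf(
    "<activation_schedule> %d events over %.5g ms (E %.3g Hz, I %.3g Hz)%s%s\n",
    nrow(x$events), x$duration, x$rates[["e_hz"]], x$rates[["i_hz"]],
    if (is.null(x$strong_fraction)) "" else
      sprintf("; strong fraction %.2f", x$strong_fraction),
    if (is.null(x$bump)) "" else
      sprintf("; %d bumps (tau %.3g ms, factor %.3g)",
              length(x$bump$onsets), x$bump$tau, x$bump$factor)))
  invisible(x)
}

#' Bump windows of a schedule
#'
#' @param schedule An [make_schedule()] result with a bump specification.
#' @return A tibble with `bump`, `t_on`, `t_off` (the spike-attribution
#'   window of each bump).
#' @export
bump_windows <- function(schedule) {
  if (is.null(schedule$bump)) abort("schedule has no bumps")
  tibble(bump = seq_along(schedule$bump$onsets),
         t_on = schedule$bump$onsets,
         t_off = schedule$bump$onsets + schedule$bump$window)
}
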