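#' Shot-noise variance of a synaptic current
#'
#' Closed-form variance of the current produced by `n_events`
#' exponentially decaying synaptic events (decay constant `tau`, mean
#' amplitude `amp_mean`, amplitude coefficient of variation `cv`) whose
#' onset times are uniform over an interval of length `interval`:
#'
#' \deqn{\sigma^2 = \bar\omega^2 N \frac{\tau}{T}
#'   \left(\frac{1 + CV^2}{2} - \frac{\tau}{T}\right)}
#'
#' This is the leading-order expansion in `tau/T` of the within-window
#' variance of the summed current (Campbell's theorem with the finite
#' -window mean correction) and is verified in the test suite against a
#' brute-force event-superposition simulation.  The quadratic dependence
#' on the mean amplitude is what makes whole-cell amplitude scaling act
#' equally on the mean and the SD of the net synaptic current, while
#' changing the event count `N` only scales the variance linearly.
#'
#' @param amp_mean Mean event amplitude (pA).
#' @param n_events Number of events in the interval.
#' @param tau Decay time constant (ms).
#' @param interval Interval length `T` (ms, > 0).  The approximation
#'   requires `tau << T`; a warning is given for `tau/interval > 0.1`.
#' @param cv Coefficient of variation of the event amplitudes.
#' @return Variance in pA^2.
#' @export
shot_noise_variance <- function(amp_mean, n_events, tau, interval, cv = 0) {
  if (interval <= 0) abort("`interval` must be positive")
  stopifnot(tau > 0, n_events >= 0, cv >= 0)
  r <- tau / interval
  if (any(r > 0.1)) {
    warn("tau/T > 0.1: outside the validity range of the approximation")
  }
  amp_mean^2 * n_events * r * ((1 + cv^2) / 2 - r)
}

#' Gaussian threshold-linear firing rate
#'
#' Expected firing rate of a threshold-linear neuron driven by a Gaussian
#' net synaptic current: below threshold `theta` the rate is zero, above
#' it the rate grows linearly with gain `beta`, and the current is
#' `X ~ Normal(i_mean, sigma^2)`.  The closed form is the Gaussian
#' positive-part expectation
#' `F = beta * (sigma * phi(z) + (i_mean - theta) * Phi(z))` with
#' `z = (i_mean - theta)/sigma`, equivalently written with `erf`.  At
#' `sigma = 0` the degenerate limit `beta * max(i_mean - theta, 0)` is
#' returned.
#'
#' @param i_mean Mean net synaptic current (current units).
#' @param sigma SD of the net synaptic current (>= 0), same units.
#' @param theta Threshold current, same units.
#' @param beta Linear gain, Hz per current unit (> 0).
#' @return Firing rate in Hz (vectorised over the inputs).
#' @export
rate_threshold_linear <- function(i_mean, sigma, theta, beta = 1) {
  stopifnot(all(sigma >= 0), all(beta > 0))
  d <- i_mean - theta
  z <- d / sigma            # +-Inf at sigma = 0 gives the linear limit
  z[is.nan(z)] <- 0         # 0/0: exactly at threshold with sigma = 0
  beta * (sigma * dnorm(z) + d * pnorm(z))
}

#' Firing-rate amplification under joint mean/SD scaling
#'
#' Ratio of the Gaussian threshold-linear rate after and before scaling
#' both the mean and the SD of the net synaptic current by `k`, the
#' signature of whole-cell balanced amplification.  The gain `beta`
#' cancels.  For `theta = 0` the rate is homogeneous of degree 1 in
#' `(i_mean, sigma)` and the ratio is exactly `k`; far above threshold it
#' converges to `k` (linear regime).
#'
#' @inheritParams rate_threshold_linear
#' @param k Scaling factor applied jointly to `i_mean` and `sigma`.
#' @return The rate ratio (vectorised).
#' @export
amplification_factor <- function(i_mean, sigma, theta, k) {
  f0 <- rate_threshold_linear(i_mean, sigma, theta)
  if (any(f0 <= 0)) abort("baseline rate is zero: amplification undefined")
  rate_threshold_linear(k * i_mean, k * sigma, theta) / f0
}

#' Amplification-factor sweep over excitability and input strength
#'
#' Evaluates the whole-cell amplification ratio of the Gaussian
#' threshold-linear rate on a grid of intrinsic excitability
#' (`theta/sigma`) and mean input strength (`i_mean/sigma`), and
#' normalises each ratio by its row mean to expose how nearly independent
#' of input strength the amplification is away from threshold.
#'
#' @param theta_over_sigma Grid of threshold-to-fluctuation ratios.
#' @param i_over_sigma Grid of mean-input-to-fluctuation ratios.
#' @param k Joint scaling factor.
#' @return A tibble with `theta_over_sigma`, `i_over_sigma`, `ratio`,
#'   `row_mean` (mean ratio at that excitability) and `ratio_norm`
#'   (`ratio/row_mean`).
#' @export
amplification_sweep <- function(theta_over_sigma = seq(-1, 4, by = 0.25),
                                i_over_sigma = seq(-0.1, 0.9, by = 0.05),
                                k = 1.7) {
  grid <- tidyr::expand_grid(theta_over_sigma = theta_over_sigma,
                             i_over_sigma = i_over_sigma)
  grid <- dplyr::mutate(grid,
                        ratio = amplification_factor(.data$i_over_sigma, 1,
                                                     .data$theta_over_sigma,
                                                     k))
  grid |>
    dplyr::group_by(.data$theta_over_sigma) |>
    dplyr::mutate(row_mean = mean(.data$ratio),
                  ratio_norm = .data$ratio / .data$row_mean) |>
    dplyr::ungroup()
}

#' Spike probability of brief activity bumps before and after amplification
#'
#' For each point of a grid over mean input (`i_over_sigma`) and threshold
#' (`theta_over_sigma`), sets the linear gain `beta` so that the rate at a
#' current `3*sigma` above threshold equals `max_rate` (the physiological
#' ceiling before sodium-channel inactivation), computes the Gaussian
#' threshold-linear rate before and after scaling `(i_mean, sigma)` by
#' `k`, and converts each rate to a per-bump spike probability
#' `P = 1 - exp(-F * window)` (Poisson spiking within a bump window).
#'
#' @inheritParams amplification_sweep
#' @param max_rate Rate ceiling in Hz used to set `beta` (one value per
#'   condition; conventionally 100 or 150).
#' @param window Bump window, ms (> 0).
#' @param sigma Fluctuation SD on the current scale (cancels from `P`
#'   only through `beta`; kept explicit for clarity).
#' @return A tibble with the grid, `beta`, `rate_before`, `rate_after`
#'   (Hz), `p_before`, `p_after`.
#' @export
bump_probability_sweep <- function(i_over_sigma = seq(0.4, 0.9, by = 0.1),
                                   theta_over_sigma = seq(0.5, 3.7,
                                                          by = 0.4),
                                   max_rate = c(100, 150), window = 30,
                                   k = 1.7, sigma = 1) {
  if (window <= 0) abort("`window` must be positive")
  grid <- tidyr::expand_grid(i_over_sigma = i_over_sigma,
                             theta_over_sigma = theta_over_sigma,
                             max_rate = max_rate)
  grid |>
    dplyr::mutate(
      beta = .data$max_rate /
        rate_threshold_linear(.data$theta_over_sigma * sigma + 3 * sigma,
                              sigma, .data$theta_over_sigma * sigma),
      rate_before = rate_threshold_linear(.data$i_over_sigma * sigma,
                                          sigma,
                                          .data$theta_over_sigma * sigma,
                                          .data$beta),
      rate_after = rate_threshold_linear(k * .data$i_over_sigma * sigma,
                                         k * sigma,
                                         .data$theta_over_sigma * sigma,
                                         .data$beta),
      p_before = 1 - exp(-.data$rate_before * window / 1000),
      p_after = 1 - exp(-.data$rate_after * window / 1000))
}
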