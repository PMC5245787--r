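#' Preprocess miniature-event waveforms for NSFA
#'
#' Applies the standard peak-scaled NSFA preprocessing to an ensemble of
#' event traces: events whose measured 10-90% rise time is not below
#' `rise_limit` (electrotonically remote events) are discarded; the
#' survivors are baseline-subtracted, aligned on their (smoothed) peak and
#' scaled so that each trace's peak equals the ensemble mean peak
#' amplitude; the background variance `sigma_b^2` is estimated from the
#' pre-event baseline window.
#'
#' @param waveforms An [synth_nsfa_waveforms()] object, or a list with
#'   `time` (ms) and `current` (time x events matrix, pA).
#' @param dt Sample interval, ms (taken from the object when present);
#'   must be <= 0.2 ms.
#' @param rise_limit 10-90% rise-time acceptance limit, ms.
#' @param baseline_ms Length of the pre-event window used for the
#'   background-variance estimate, ms.
#' @param min_events Minimum number of surviving events for a fit.
#' @return A list of class `aligned_events`: `scaled` (matrix, aligned and
#'   peak-scaled traces), `mean_waveform`, `peak_index`, `sigma_b2`,
#'   `n_events`, `dt`, `rise_times`.
#' @export
preprocess_events <- function(waveforms, dt = NULL, rise_limit = 1.5,
                              baseline_ms = 5, min_events = 20) {
  cur <- waveforms$current
  dt <- dt %||% waveforms$dt
  if (is.null(dt) || dt <= 0 || dt > 0.2) {
    abort("`dt` must be positive and <= 0.2 ms for rise-time resolution")
  }
  stopifnot(is.matrix(cur))
  nb <- max(2L, floor(baseline_ms / dt))
  nb <- min(nb, nrow(cur) - 2L)
  rise <- apply(cur, 2, rise_time_1090, dt = dt, baseline_n = nb)
  keep <- !is.na(rise) & rise < rise_limit
  if (sum(keep) == 0) abort("no events pass the rise-time filter")
  if (sum(keep) < min_events) {
    abort(sprintf("only %d events pass the rise-time filter (need >= %d)",
                  sum(keep), min_events))
  }
  cur <- cur[, keep, drop = FALSE]
  base <- colMeans(cur[seq_len(nb), , drop = FALSE])
  cur <- sweep(cur, 2, base)
  sigma_b2 <- mean(apply(cur[seq_len(nb), , drop = FALSE], 2, var))
  # peak index per event from a 3-point smoothed trace
  n <- nrow(cur)
  sm <- (rbind(cur[1, ], cur[-n, ]) + cur + rbind(cur[-1, ], cur[n, ])) / 3
  ipk <- apply(sm, 2, which.max)
  peaks <- cur[cbind(ipk, seq_len(ncol(cur)))]
  if (any(peaks <= 0)) {
    ok <- peaks > 0
    cur <- cur[, ok, drop = FALSE]; ipk <- ipk[ok]; peaks <- peaks[ok]
  }
  target_peak <- mean(peaks)
  # align all traces on a common peak index
  ref <- round(stats::median(ipk))
  aligned <- matrix(NA_real_, nrow = n, ncol = ncol(cur))
  for (j in seq_len(ncol(cur))) {
    shift <- ipk[j] - ref
    src <- seq_len(n) + shift
    valid <- src >= 1 & src <= n
    aligned[which(valid), j] <- cur[src[valid], j]
  }
  scaled <- sweep(aligned, 2, target_peak / peaks, `*`)
  mean_wf <- rowMeans(scaled, na.rm = TRUE)
  structure(list(scaled = scaled, mean_waveform = mean_wf,
                 peak_index = ref, sigma_b2 = sigma_b2,
                 n_events = ncol(scaled), dt = dt,
                 rise_times = rise[keep]),
            class = "aligned_events")
}

#' @export
print.aligned_events <- function(x, ...) {
  cat(sprintf(
    "<aligned_events> %d events, peak %.3g pA at sample %d, background variance %.3g pA^2\n",
    x$n_events, max(x$mean_waveform), x$peak_index, x$sigma_b2))
  invisible(x)
}

#' Mean-current / ensemble-variance profile of the decay phase
#'
#' Divides the decay phase of the aligned ensemble -- from the peak to the
#' point where the mean current first falls below `decay_floor` of the
#' peak -- into `n_bins` equal-time bins and returns, per bin, the mean
#' current `I_k` and the ensemble variance `var_k` of the traces about the
#' scaled mean waveform.
#'
#' @param aligned An [preprocess_events()] result.
#' @param n_bins Number of decay bins.
#' @param decay_floor Fraction of the peak mean current at which the decay
#'   phase ends.
#' @return A tibble with `bin`, `I` (pA) and `variance` (pA^2).
#' @export
decay_variance_profile <- function(aligned, n_bins = 30, decay_floor = 0.1) {
  stopifnot(inherits(aligned, "aligned_events"))
  mw <- aligned$mean_waveform
  ipk <- aligned$peak_index
  pk <- mw[ipk]
  below <- which(mw < decay_floor * pk & seq_along(mw) > ipk)
  iend <- if (length(below)) below[1] else length(mw)
  if (iend - ipk < n_bins) {
    abort(sprintf("decay phase has %d samples, fewer than %d bins",
                  iend - ipk, n_bins))
  }
  edges <- round(seq(ipk, iend, length.out = n_bins + 1))
  purrr::map_dfr(seq_len(n_bins), function(k) {
    rows <- seq(edges[k], max(edges[k + 1] - 1L, edges[k]))
    seg <- aligned$scaled[rows, , drop = FALSE]
    dev <- sweep(seg, 1, mw[rows])
    tibble(bin = k, I = mean(mw[rows]),
           variance = mean(apply(dev, 1, var, na.rm = TRUE)))
  })
}

#' Fit the peak-scaled NSFA parabola
#'
#' Least-squares fit of the single-channel relation
#' `variance = i * I - I^2 / N + sigma_b^2` to the decay-phase bin points,
#' with the background variance subtracted (not fitted).  The fit quality
#' `R` is the Pearson correlation between observed and fitted variances;
#' fits with `R <= r_accept` or non-positive `i` or `N` are flagged
#' rejected, the conventional acceptance gate for reporting single-channel
#' estimates.
#'
#' @param bin_points A tibble from [decay_variance_profile()] (columns `I`,
#'   `variance`).
#' @param sigma_b2 Background variance, pA^2.
#' @param r_accept Acceptance threshold on `R`.
#' @return An object of class `nsfa_fit` with elements `i` (pA), `N`, `R`,
#'   `accepted`, `reason`, `bin_points` (with fitted values), `sigma_b2`.
#' @export
fit_nsfa <- function(bin_points, sigma_b2, r_accept = 0.85) {
  stopifnot(all(c("I", "variance") %in% names(bin_points)))
  if (nrow(bin_points) < 10) abort("need at least 10 bin points")
  span <- diff(range(bin_points$I)) / max(bin_points$I)
  if (span < 0.5) {
    warn("bin points span less than 50% of the peak amplitude")
  }
  y <- bin_points$variance - sigma_b2
  I <- bin_points$I
  fit <- lm(y ~ 0 + I + I(I^2))
  b <- coef(fit)
  i_hat <- unname(b[1])
  N_hat <- if (b[2] < 0) -1 / unname(b[2]) else NA_real_
  fitted_var <- fitted(fit) + sigma_b2
  R <- suppressWarnings(cor(bin_points$variance, fitted_var))
  if (!is.finite(R)) R <- 0
  reason <- NULL
  if (!is.finite(N_hat) || i_hat <= 0) {
    reason <- "non-physical fitted parameters (i <= 0 or N <= 0)"
  } else if (R <= r_accept) {
    reason <- sprintf("fit quality R = %.3f <= %.2f", R, r_accept)
  }
  structure(list(i = i_hat, N = N_hat, R = R,
                 accepted = is.null(reason),
                 reason = reason %||% "accepted",
                 bin_points = dplyr::mutate(bin_points,
                                            fitted = fitted_var),
                 sigma_b2 = sigma_b2),
            class = "nsfa_fit")
}

#' @export
print.nsfa_fit <- function(x, ...) {
  cat(sprintf(
    "<nsfa_fit> i = %.4g pA, N = %.4g channels, R = %.3f [%s]\n",
    x$i, x$N, x$R, if (x$accepted) "accepted" else x$reason))
  invisible(x)
}

#' @export
tidy.nsfa_fit <- function(x, ...) x$bin_points

#' @export
glance.nsfa_fit <- function(x, ...) {
  tibble(i = x$i, N = x$N, R = x$R, sigma_b2 = x$sigma_b2,
         accepted = x$accepted)
}

#' Full peak-scaled NSFA pipeline
#'
#' Convenience wrapper: [preprocess_events()] then
#' [decay_variance_profile()] then [fit_nsfa()].
#'
#' @inheritParams preprocess_events
#' @inheritParams decay_variance_profile
#' @inheritParams fit_nsfa
#' @return An `nsfa_fit` with an added `n_events` element.
#' @export
nsfa <- function(waveforms, dt = NULL, rise_limit = 1.5, baseline_ms = 5,
                 n_bins = 30, decay_floor = 0.1, r_accept = 0.85) {
  aligned <- preprocess_events(waveforms, dt = dt, rise_limit = rise_limit,
                               baseline_ms = baseline_ms)
  prof <- decay_variance_profile(aligned, n_bins = n_bins,
                                 decay_floor = decay_floor)
  fit <- fit_nsfa(prof, aligned$sigma_b2, r_accept = r_accept)
  fit$n_events <- aligned$n_events
  fit
}
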