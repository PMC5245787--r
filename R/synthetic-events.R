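#' Miniature-event amplitude model
#'
#' Parametric model of a per-cell miniature postsynaptic current (mEPSC or
#' mIPSC) amplitude distribution: a Gaussian body truncated to
#' `[detection_floor, tail_start]` mixed with an exponential tail above
#' `tail_start`.  The body emulates the "weak synapse" section of an
#' empirical mini amplitude histogram and the tail its strong-synapse part;
#' the `tail_start` cut (13 pA by default) is the conventional strong/weak
#' boundary.  All samples are strictly positive and at least
#' `detection_floor`.
#'
#' @param body_mean Mean of the (untruncated) Gaussian body, pA.
#' @param body_sd Standard deviation of the Gaussian body, pA.
#' @param tail_weight Probability mass of the exponential tail, in `[0, 1]`.
#'   `tail_weight = 0` reduces the model to the truncated-Gaussian body.
#' @param tail_scale Scale (mean excess over `tail_start`) of the
#'   exponential tail, pA.
#' @param tail_start Amplitude at which the tail begins, pA.
#' @param detection_floor Smallest detectable amplitude, pA; the body is
#'   truncated below at this value.
#' @return An object of class `amplitude_model`.
#' @examples
#' m <- amplitude_model()
#' mean(m)                       # analytic mean, pA
#' ev <- sample_cell_events(m, 200)
#' mean(ev$amplitude_pA)
#' @export
amplitude_model <- function(body_mean = 8, body_sd = 2.5, tail_weight = 0.15,
                            tail_scale = 3, tail_start = 13,
                            detection_floor = 5) {
  assert_scalar_number(body_mean, "body_mean", lower = 0)
  assert_scalar_number(body_sd, "body_sd", lower = 1e-12)
  assert_scalar_number(tail_weight, "tail_weight", lower = 0, upper = 1)
  assert_scalar_number(tail_scale, "tail_scale", lower = 1e-12)
  assert_scalar_number(detection_floor, "detection_floor", lower = 0)
  if (tail_start <= detection_floor) {
    abort("`tail_start` must exceed `detection_floor`.")
  }
  structure(
    list(body_mean = body_mean, body_sd = body_sd, tail_weight = tail_weight,
         tail_scale = tail_scale, tail_start = tail_start,
         detection_floor = detection_floor),
    class = "amplitude_model")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat(sprintf(
    "<amplitude_model> body N(%.3g, %.3g^2) pA on [%.3g, %.3g]; tail %.3g Exp(%.3g) above %.3g pA; mean %.3g pA\n",
    x$body_mean, x$body_sd, x$detection_floor, x$tail_start,
    x$tail_weight, x$tail_scale, x$tail_start, mean(x)))
  invisible(x)
}

# Mean of a Normal(mu, sd) truncated to [a, b].
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

#' @describeIn amplitude_model Analytic mean amplitude (pA) of the mixture.
#' @param x An `amplitude_model`.
#' @param ... Unused.
#' @export
mean.amplitude_model <- function(x, ...) {
  body <- truncnorm_mean(x$body_mean, x$body_sd, x$detection_floor,
                         x$tail_start)
  (1 - x$tail_weight) * body +
    x$tail_weight * (x$tail_start + x$tail_scale)
}

# Draw n base amplitudes from an amplitude_model (no amplification applied).
# Inverse-CDF sampling so that the number of RNG draws is deterministic.
draw_base_amplitudes <- function(model, n) {
  tail <- runif(n) < model$tail_weight
  u <- runif(n)
  lo <- pnorm((model$detection_floor - model$body_mean) / model$body_sd)
  hi <- pnorm((model$tail_start - model$body_mean) / model$body_sd)
  body <- model$body_mean +
    model$body_sd * qnorm(lo + u * (hi - lo))
  x <- ifelse(tail,
              model$tail_start + rexp(n, rate = 1 / model$tail_scale),
              body)
  # numerical safety at the truncation boundaries
  pmax(x, model$detection_floor)
}

#' Sample miniature events for one cell
#'
#' Draws `n` amplitudes from an [amplitude_model()] and multiplies every
#' draw by `amplification`, emulating a cell whose synaptic single-channel
#' conductance has been scaled whole-cell by that factor.  For a fixed
#' `seed` the base draws are identical across `amplification` values, so
#' `amplification = 2` returns exactly twice the `amplification = 1`
#' sample.
#'
#' @param model An [amplitude_model()].
#' @param n Number of events (>= 1).
#' @param amplification Whole-cell multiplier (>= 1) applied to every draw.
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble with column `amplitude_pA`.
#' @export
sample_cell_events <- function(model, n, amplification = 1, seed = NULL) {
  stopifnot(inherits(model, "amplitude_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive count.")
  }
  assert_scalar_number(amplification, "amplification", lower = 1)
  amps <- with_seed_maybe(seed, draw_base_amplitudes(model, as.integer(n)))
  tibble(amplitude_pA = amps * amplification)
}

# Accept a numeric vector, or a data frame with an `amplitude_pA` column,
# as an event set.
event_amplitudes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x) && "amplitude_pA" %in% names(x)) {
    return(as.numeric(x$amplitude_pA))
  }
  abort("expected a numeric vector or a data frame with an `amplitude_pA` column")
}

#' Generate a pre/post blocker pair with known ground truth
#'
#' Simulates the amplitudes recorded from one cell before (`pre`) and after
#' (`post`) a blocker that divides the amplitude of a fraction `x` of events
#' by `a`.  Two generative conventions are provided:
#'
#' * `"mixture-on-pre"` (default): `post` is i.i.d. from the base model and
#'   `pre` is a mixture in which each event is, with probability `x`, an
#'   `a`-fold amplified base draw.  Under this convention the expected ratio
#'   of means is exactly `y = (1 - x) + x * a`, and the multiplicative
#'   reversal procedure is exact.
#' * `"fully-doubled-pre"`: `pre` is `a` times the base model (a fully
#'   amplified cell) and `post` is a mixture in which a fraction `x` of
#'   events have been divided back by `a` (partial blocker action).
#'
#' @param model An [amplitude_model()] describing the base (naive)
#'   distribution.
#' @param x Fraction of events affected by the blocker, in `[0, 1]`.
#' @param a Per-event amplification/division factor (> 1).
#' @param n_pre,n_post Event counts for the two phases.
#' @param convention `"mixture-on-pre"` or `"fully-doubled-pre"`.
#' @param seed Optional integer seed.
#' @return A tibble of class `blocker_pair` with columns `phase`
#'   (`"pre"`/`"post"`) and `amplitude_pA`, and attributes `true_x`,
#'   `true_a`, `convention`.
#' @export
make_blocker_pair <- function(model, x, a = 2, n_pre = 200, n_post = 200,
                              convention = c("mixture-on-pre",
                                             "fully-doubled-pre"),
                              seed = NULL) {
  stopifnot(inherits(model, "amplitude_model"))
  assert_scalar_number(x, "x", lower = 0, upper = 1)
  assert_scalar_number(a, "a", lower = 1 + 1e-12)
  if (n_pre < 1 || n_post < 1) abort("phase event counts must be positive")
  convention <- match.arg(convention)
  out <- with_seed_maybe(seed, {
    if (convention == "mixture-on-pre") {
      base_pre <- draw_base_amplitudes(model, n_pre)
      affected <- runif(n_pre) < x
      pre <- ifelse(affected, a * base_pre, base_pre)
      post <- draw_base_amplitudes(model, n_post)
    } else {
      pre <- a * draw_base_amplitudes(model, n_pre)
      base_post <- a * draw_base_amplitudes(model, n_post)
      affected <- runif(n_post) < x
      post <- ifelse(affected, base_post / a, base_post)
    }
    list(pre = pre, post = post)
  })
  res <- tibble(
    phase = rep(c("pre", "post"), c(n_pre, n_post)),
    amplitude_pA = c(out$pre, out$post))
  attr(res, "true_x") <- x
  attr(res, "true_a") <- a
  attr(res, "convention") <- convention
  class(res) <- c("blocker_pair", class(res))
  res
}

#' Split a blocker pair into its two phases
#'
#' @param pair A [make_blocker_pair()] result, or any data frame with
#'   `phase` and `amplitude_pA` columns.
#' @return A list with numeric elements `pre` and `post`.
#' @export
pair_phases <- function(pair) {
  stopifnot(is.data.frame(pair), all(c("phase", "amplitude_pA") %in% names(pair)))
  list(pre = pair$amplitude_pA[pair$phase == "pre"],
       post = pair$amplitude_pA[pair$phase == "post"])
}

#' Generate a population cohort of cells
#'
#' Builds a labelled multi-group data set of per-cell miniature-event
#' amplitude samples in which a randomly chosen subset of the trained (and
#' optionally pseudo-trained) cells has every event amplitude multiplied by
#' `amplification_factor`, emulating cells that underwent whole-cell
#' amplification.  Event counts per cell are drawn uniformly from
#' `events_per_cell`, the 80-300 range typical of a stable miniature-event
#' recording.
#'
#' @param n_cells Named counts per group, e.g.
#'   `c(naive = 12, pseudo = 8, trained = 16)`; each group needs >= 2 cells.
#' @param amplified_fraction Fraction of eligible cells flagged amplified.
#' @param amplification_factor Whole-cell multiplier for amplified cells.
#' @param events_per_cell Integer range (length 2) of events per cell.
#' @param model Base [amplitude_model()] shared by all cells.
#' @param amplify_groups Groups whose cells may be amplified.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   data sets.
#' @return A tibble of class `mini_population` with columns `cell_id`,
#'   `group`, `amplitude_pA`; the per-cell ground truth (including the
#'   `amplified` flag) is attached as attribute `"cells"` and retrievable
#'   with [population_cells()].
#' @export
generate_population <- function(n_cells = c(naive = 12, pseudo = 8, trained = 16),
                                amplified_fraction = 0.35,
                                amplification_factor = 2,
                                events_per_cell = c(80L, 300L),
                                model = amplitude_model(),
                                amplify_groups = "trained",
                                seed = NULL) {
  if (is.null(names(n_cells)) || any(!nzchar(names(n_cells)))) {
    abort("`n_cells` must be a named vector of group sizes.")
  }
  if (any(n_cells < 2)) {
    abort("each group needs at least 2 cells (downstream clustering).")
  }
  assert_scalar_number(amplified_fraction, "amplified_fraction", 0, 1)
  assert_scalar_number(amplification_factor, "amplification_factor", lower = 1)
  stopifnot(length(events_per_cell) == 2L, events_per_cell[1] >= 1,
            events_per_cell[2] >= events_per_cell[1])
  with_seed_maybe(seed, {
    cells <- tibble(
      group = rep(names(n_cells), n_cells),
      cell_id = sprintf("%s_%02d", .data$group,
                        unlist(lapply(n_cells, seq_len))),
      n_events = sample(seq(events_per_cell[1], events_per_cell[2]),
                        sum(n_cells), replace = TRUE),
      amplified = FALSE)
    eligible <- which(cells$group %in% amplify_groups)
    n_amp <- round_half_even(amplified_fraction * length(eligible))
    if (n_amp > 0) {
      cells$amplified[sample(eligible, n_amp)] <- TRUE
    }
    events <- purrr::pmap_dfr(
      cells[c("cell_id", "group", "n_events", "amplified")],
      function(cell_id, group, n_events, amplified) {
        amp <- draw_base_amplitudes(model, n_events) *
          if (amplified) amplification_factor else 1
        tibble(cell_id = cell_id, group = group, amplitude_pA = amp)
      })
    attr(events, "cells") <- cells
    attr(events, "model") <- model
    class(events) <- c("mini_population", class(events))
    events
  })
}

#' @rdname generate_population
#' @param population A `mini_population`.
#' @export
population_cells <- function(population) {
  cells <- attr(population, "cells")
  if (is.null(cells)) abort("no ground-truth cell table attached")
  cells
}
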