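#' Per-cell blocker effect
#'
#' Quantifies the effect of a blocker on one cell as the ratio of the mean
#' (and of the sample SD, `n - 1` denominator) of the event amplitudes
#' recorded before drug application to those recorded after.  A purely
#' multiplicative process moves both ratios together, which is what makes
#' the (mean ratio, SD ratio) pair a robust per-cell signature.
#'
#' @param pre,post Amplitude samples (numeric vectors or data frames with
#'   `amplitude_pA`), >= 2 events each.
#' @param cell_id Optional cell label carried into the output.
#' @return A one-row tibble with `cell_id`, `y_mean`, `y_sd`, `n_pre`,
#'   `n_post` and a logical `undefined` flag (zero post mean or SD).
#' @export
blocker_effect <- function(pre, post, cell_id = NA_character_) {
  pre <- event_amplitudes(pre)
  post <- event_amplitudes(post)
  if (length(pre) < 2 || length(post) < 2) {
    abort("each phase needs at least 2 events")
  }
  mpost <- mean(post); spost <- sd(post)
  undefined <- mpost == 0 || spost == 0
  tibble(cell_id = cell_id,
         y_mean = if (mpost == 0) NA_real_ else mean(pre) / mpost,
         y_sd = if (spost == 0) NA_real_ else sd(pre) / spost,
         n_pre = length(pre), n_post = length(post),
         undefined = undefined)
}

#' Blocker effects for every cell of an event table
#'
#' @param events A data frame with columns `cell_id`, `phase`
#'   (`"pre"`/`"post"`) and `amplitude_pA`.
#' @return A tibble with one [blocker_effect()] row per cell.
#' @export
blocker_effects <- function(events) {
  stopifnot(all(c("cell_id", "phase", "amplitude_pA") %in% names(events)))
  events |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      blocker_effect(d$amplitude_pA[d$phase == "pre"],
                     d$amplitude_pA[d$phase == "post"])[-1]
    }) |>
    dplyr::ungroup()
}

#' Fraction of events affected by a blocker
#'
#' Under the model in which a blocker divides the amplitude of a fraction
#' `x` of the events by a factor `a` (leaving the rest untouched), the
#' blocker effect on the mean is `y = (1 - x) + x * a`, so the affected
#' fraction is recovered as `x = (y - 1) / (a - 1)`.
#'
#' @param y Blocker effect (ratio of mean amplitude before / after),
#'   vectorised.
#' @param a Per-event division factor (> 1).
#' @return A tibble with `y`, `x` (clipped to `[0, 1]`), the raw `x_raw`,
#'   and a `clipped` flag for estimates outside `[0, 1]`.
#' @export
affected_fraction <- function(y, a = 2) {
  assert_scalar_number(a, "a", lower = 1 + 1e-12)
  x_raw <- (y - 1) / (a - 1)
  tibble(y = y, x = pmin(pmax(x_raw, 0), 1), x_raw = x_raw,
         clipped = x_raw < 0 | x_raw > 1)
}

#' Two-cluster segregation of blocker effects
#'
#' Partitions cells into an "affected" and a "non-affected" cluster by
#' 2-means on the standardised `(y_mean, y_sd)` plane (50 restarts under a
#' fixed seed), labelling as affected the cluster with the larger centroid
#' mean ratio, and scores the separation with the mean silhouette width
#' (Euclidean distance on the standardised features).
#'
#' @param effects A data frame as returned by [blocker_effects()]
#'   (columns `y_mean`, `y_sd`, optionally `cell_id`).
#' @param n_restart Number of k-means restarts.
#' @param seed Seed for the restarts (fixed default: deterministic result).
#' @return A list of class `effect_clusters`: `labels` (tibble of
#'   `cell_id`, `y_mean`, `y_sd`, `cluster` in `{"affected",
#'   "non-affected"}`), `mean_silhouette`, `centroids` (on the original
#'   ratio scale), and a `degenerate` flag when all points coincide.
#' @export
cluster_effects <- function(effects, n_restart = 50, seed = 1L) {
  stopifnot(all(c("y_mean", "y_sd") %in% names(effects)))
  eff <- effects[complete.cases(effects[c("y_mean", "y_sd")]), ]
  if (nrow(eff) < 4) abort("need at least 4 cells to cluster")
  xy <- as.matrix(eff[c("y_mean", "y_sd")])
  if (all(apply(xy, 2, function(v) diff(range(v)) == 0))) {
    return(structure(list(labels = NULL, mean_silhouette = NA_real_,
                          centroids = NULL, degenerate = TRUE),
                     class = "effect_clusters"))
  }
  z <- scale(xy)
  z[, apply(xy, 2, function(v) diff(range(v)) == 0)] <- 0
  km <- with_seed_maybe(seed, kmeans(z, centers = 2, nstart = n_restart))
  affected_id <- which.max(tapply(eff$y_mean, km$cluster, mean))
  cluster <- ifelse(km$cluster == affected_id, "affected", "non-affected")
  sil <- cluster::silhouette(km$cluster, stats::dist(z))
  cent <- dplyr::bind_cols(
    cluster = ifelse(seq_len(2) == affected_id, "affected", "non-affected"),
    as_tibble(do.call(rbind, lapply(split(as.data.frame(xy), km$cluster),
                                    colMeans))))
  labels <- tibble(
    cell_id = if ("cell_id" %in% names(eff)) eff$cell_id else
      seq_len(nrow(eff)),
    y_mean = eff$y_mean, y_sd = eff$y_sd, cluster = cluster)
  structure(list(labels = labels,
                 mean_silhouette = mean(sil[, "sil_width"]),
                 centroids = cent, degenerate = FALSE),
            class = "effect_clusters")
}

#' @export
print.effect_clusters <- function(x, ...) {
  if (x$degenerate) {
    cat("<effect_clusters> degenerate: identical points, silhouette undefined\n")
    return(invisible(x))
  }
  n <- table(x$labels$cluster)
  cat(sprintf(
    "<effect_clusters> affected: %d cells, non-affected: %d; mean silhouette %.2f\n",
    n[["affected"]], n[["non-affected"]], x$mean_silhouette))
  invisible(x)
}

#' @export
tidy.effect_clusters <- function(x, ...) {
  if (x$degenerate) return(tibble())
  x$labels
}

#' @export
glance.effect_clusters <- function(x, ...) {
  tibble(mean_silhouette = x$mean_silhouette, degenerate = x$degenerate,
         n_affected = if (x$degenerate) NA_integer_ else
           sum(x$labels$cluster == "affected"))
}

#' Amplitude distribution curve
#'
#' Normalised amplitude histogram (relative frequencies summing to 1) on a
#' regular grid of `bin_width`-wide bins covering `[0, max]`.
#'
#' @param events Amplitudes (vector or data frame with `amplitude_pA`).
#' @param bin_width Bin width, pA (> 0).
#' @param max_amplitude Optional upper edge of the grid (defaults to the
#'   sample maximum); use a shared value when curves are to be averaged.
#' @return A tibble with `bin_center` (pA) and `rel_freq`.
#' @export
distribution_curve <- function(events, bin_width = 1, max_amplitude = NULL) {
  x <- event_amplitudes(events)
  if (length(x) == 0) abort("no events")
  if (bin_width <= 0) abort("`bin_width` must be positive")
  top <- max(max_amplitude %||% max(x), max(x))
  breaks <- seq(0, top + bin_width, by = bin_width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  tibble(bin_center = breaks[-length(breaks)] + bin_width / 2,
         rel_freq = counts / sum(counts))
}

#' Distribution curve averaged across cells
#'
#' Computes per-cell [distribution_curve()]s on a shared grid and averages
#' them pointwise, so that every cell contributes equally regardless of its
#' event count.
#'
#' @param events Data frame with `cell_id` and `amplitude_pA`.
#' @inheritParams distribution_curve
#' @return A tibble with `bin_center`, `rel_freq` (mean across cells) and
#'   `n_cells`.
#' @export
average_distribution_curve <- function(events, bin_width = 1) {
  stopifnot(all(c("cell_id", "amplitude_pA") %in% names(events)))
  top <- max(events$amplitude_pA)
  curves <- events |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ distribution_curve(.x$amplitude_pA, bin_width,
                                             max_amplitude = top)) |>
    dplyr::ungroup()
  curves |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::summarise(rel_freq = mean(.data$rel_freq),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Computational reversal of a blocker effect
#'
#' Reconstructs the pre-blocker amplitude distribution from the post-blocker
#' events under a candidate generative model and tests the reconstruction
#' against the recorded pre events with the permutation Cramer-von Mises
#' test.  Models:
#'
#' * `"multiplicative"`: the fraction of affected events is estimated from
#'   the observed mean ratio as `x = (y - 1)/(a - 1)`; `round(x * n)`
#'   randomly chosen post events are multiplied by `a`.
#' * `"additive"`: every post event is increased by an independent uniform
#'   draw from `[0, 2 * (mean(pre) - mean(post))]`, which restores the mean
#'   but not the shape.
#' * `"triple"`: as multiplicative but with the factor forced to 3 (and `x`
#'   recomputed with `a = 3`), a deliberately wrong multiplicative model.
#'
#' @param pre,post Amplitude samples for the two phases.
#' @param model_tag `"multiplicative"`, `"additive"` or `"triple"`.
#' @param a Division factor of the blocker under the multiplicative model.
#' @param x Affected fraction; defaults to the estimate from the data.
#' @param n_perm,seed Passed to [cvm_two_sample()]; `seed` also fixes the
#'   random choice of events to multiply.
#' @return A list of class `reversal_outcome`: `reconstructed` amplitudes
#'   (same count as `post`), `model_tag`, `x_used`, `factor_used`,
#'   `mean_ratio` (reconstructed/pre), `cvm_statistic`, `p_value`,
#'   `difference_likelihood`.
#' @export
reverse_blocker <- function(pre, post,
                            model_tag = c("multiplicative", "additive",
                                          "triple"),
                            a = 2, x = NULL, n_perm = 9999, seed = NULL) {
  pre <- event_amplitudes(pre)
  post <- event_amplitudes(post)
  model_tag <- match.arg(model_tag)
  n <- length(post)
  y <- mean(pre) / mean(post)
  with_seed_maybe(seed, {
    if (model_tag == "additive") {
      delta <- mean(pre) - mean(post)
      reconstructed <- post + runif(n, 0, max(2 * delta, 0))
      x_used <- NA_real_; factor_used <- NA_real_
    } else {
      factor_used <- if (model_tag == "triple") 3 else a
      x_used <- x %||% affected_fraction(y, factor_used)$x
      if (x_used < 0 || x_used > 1) abort("`x` must lie in [0, 1]")
      k <- round_half_even(x_used * n)
      pick <- sample.int(n, k)
      reconstructed <- post
      reconstructed[pick] <- reconstructed[pick] * factor_used
    }
    cvm <- cvm_two_sample(reconstructed, pre, n_perm = n_perm)
    structure(list(reconstructed = reconstructed, model_tag = model_tag,
                   x_used = x_used, factor_used = factor_used,
                   mean_ratio = mean(reconstructed) / mean(pre),
                   cvm_statistic = cvm$statistic, p_value = cvm$p_value,
                   difference_likelihood = cvm$difference_likelihood),
              class = "reversal_outcome")
  })
}

#' @export
print.reversal_outcome <- function(x, ...) {
  cat(sprintf(
    "<reversal_outcome> model %s: mean ratio %.3f, CvM T = %.4g, p = %.4g (difference likelihood %.3g)\n",
    x$model_tag, x$mean_ratio, x$cvm_statistic, x$p_value,
    x$difference_likelihood))
  invisible(x)
}

#' @export
tidy.reversal_outcome <- function(x, ...) {
  tibble(model_tag = x$model_tag, x_used = x$x_used,
         factor_used = x$factor_used, mean_ratio = x$mean_ratio,
         cvm_statistic = x$cvm_statistic, p_value = x$p_value,
         difference_likelihood = x$difference_likelihood)
}

#' Reconstruction of an amplified group by doubling all naive events
#'
#' Multiplies every naive event amplitude by `factor` and compares the
#' result with a target (e.g. amplified-cluster) event set using the
#' permutation Cramer-von Mises test.
#'
#' @param naive_events,target_events Amplitude samples.
#' @param factor Whole-cell multiplication factor.
#' @inheritParams cvm_two_sample
#' @return A list of class `cvm_test` (see [cvm_two_sample()]) with an
#'   added `doubled` element holding the transformed naive amplitudes.
#' @export
naive_doubling_reconstruction <- function(naive_events, target_events,
                                          factor = 2, n_perm = 9999,
                                          seed = NULL) {
  naive <- event_amplitudes(naive_events)
  target <- event_amplitudes(target_events)
  doubled <- naive * factor
  out <- cvm_two_sample(doubled, target, n_perm = n_perm, seed = seed)
  out$doubled <- doubled
  out
}

#' Cumulative curve reconstruction from per-cell mean amplitudes
#'
#' Emulates a trained-group cumulative frequency curve of per-cell average
#' event amplitudes from naive-group cell means: a random `fraction` of the
#' naive cell means is multiplied by `factor`, the cumulative curve is
#' formed, and the procedure is repeated `n_boot` times to give a
#' reconstruction band.  When target cell means are supplied each replicate
#' is compared with them by the two-sample KS test.
#'
#' @param naive_cell_means Per-cell mean amplitudes of the reference group,
#'   pA.
#' @param fraction Fraction of cells whose mean is multiplied.
#' @param factor Multiplication factor.
#' @param target_cell_means Optional per-cell means of the group to be
#'   explained.
#' @param n_boot Number of random reconstructions.
#' @param seed Optional integer seed.
#' @return A list of class `curve_reconstruction` with `replicates`
#'   (tibble: `replicate`, `cell_mean`), `ks` (tibble of per-replicate KS
#'   results, if a target was given) and the call parameters.
#' @export
reconstruct_group_curve <- function(naive_cell_means, fraction = 0.35,
                                    factor = 2, target_cell_means = NULL,
                                    n_boot = 100, seed = NULL) {
  stopifnot(length(naive_cell_means) > 0)
  assert_scalar_number(fraction, "fraction", 0, 1)
  n <- length(naive_cell_means)
  k <- round_half_even(fraction * n)
  with_seed_maybe(seed, {
    reps <- purrr::map_dfr(seq_len(n_boot), function(b) {
      m <- naive_cell_means
      if (k > 0) {
        pick <- sample.int(n, k)
        m[pick] <- m[pick] * factor
      }
      tibble(replicate = b, cell_mean = sort(m))
    })
    ks <- NULL
    if (!is.null(target_cell_means)) {
      ks <- reps |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_modify(~ ks_two_sample(.x$cell_mean,
                                            target_cell_means)) |>
        dplyr::ungroup()
    }
    structure(list(replicates = reps, ks = ks, fraction = fraction,
                   factor = factor, n_boot = n_boot),
              class = "curve_reconstruction")
  })
}

#' @export
print.curve_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<curve_reconstruction> %d replicates, fraction %.2f x factor %.2g%s\n",
    x$n_boot, x$fraction, x$factor,
    if (is.null(x$ks)) "" else
      sprintf("; median KS p = %.3g", stats::median(x$ks$p_value))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
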