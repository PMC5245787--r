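#' Two-sample Cramer-von Mises permutation test
#'
#' Compares two samples with the Cramer-von Mises criterion
#' `T = nm/(n+m)^2 * sum_k (F1(z_k) - F2(z_k))^2`, summed over the pooled
#' observations `z_k`, with significance assessed by random permutation of
#' the sample labels.  Ties contribute through the empirical CDFs
#' evaluated at the tied value (mid-rank behaviour).  Alongside the
#' standard p-value the complementary `difference_likelihood = 1 - p` is
#' reported: the likelihood that the two distribution curves are drawn
#' from different populations, the quantity quoted when distribution
#' overlap (a high p) is the interesting outcome.
#'
#' @param s1,s2 Numeric samples (>= 5 observations each), or data frames
#'   with an `amplitude_pA` column.
#' @param n_perm Number of label permutations (a warning is given below
#'   100).
#' @param seed Optional integer seed for the permutations.
#' @return A list of class `cvm_test` with `statistic`, `p_value`,
#'   `difference_likelihood`, `n_perm`, `n1`, `n2`.
#' @export
cvm_two_sample <- function(s1, s2, n_perm = 9999, seed = NULL) {
  s1 <- event_amplitudes(s1)
  s2 <- event_amplitudes(s2)
  if (length(s1) < 5 || length(s2) < 5) {
    abort("each sample needs at least 5 observations")
  }
  if (n_perm < 100) warn("fewer than 100 permutations: p-value is coarse")
  n1 <- length(s1); n2 <- length(s2)
  pooled <- c(s1, s2)
  is1 <- rep(c(TRUE, FALSE), c(n1, n2))
  ord <- order(pooled)
  x <- pooled[ord]
  # at tied values both CDFs are evaluated after the full tie block
  tie_idx <- if (anyDuplicated(x)) {
    cummax_last(rev(!duplicated(rev(x))))
  } else {
    NULL
  }
  stat_from_labels <- function(lab1) {
    # lab1: logical, TRUE = sample 1, aligned with sorted pooled values
    f1 <- cumsum(lab1) / n1
    f2 <- cumsum(!lab1) / n2
    if (!is.null(tie_idx)) {
      f1 <- f1[tie_idx]; f2 <- f2[tie_idx]
    }
    n1 * n2 / (n1 + n2)^2 * sum((f1 - f2)^2)
  }
  observed <- stat_from_labels(is1[ord])
  perm_stats <- with_seed_maybe(seed, {
    vapply(seq_len(n_perm), function(k) {
      stat_from_labels(sample(is1)[ord])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= observed - 1e-15)) / (n_perm + 1)
  structure(list(statistic = observed, p_value = p,
                 difference_likelihood = 1 - p, n_perm = n_perm,
                 n1 = n1, n2 = n2),
            class = "cvm_test")
}

# For each position, the index of the last element of its tie block, given
# a logical marking tie-block ends on sorted data.
cummax_last <- function(last) {
  idx <- which(last)
  rep(idx, diff(c(0L, idx)))
}

#' @export
print.cvm_test <- function(x, ...) {
  cat(sprintf(
    "Two-sample Cramer-von Mises permutation test\n  T = %.5g, p = %.4g (%d permutations), difference likelihood = %.4g\n  n1 = %d, n2 = %d\n",
    x$statistic, x$p_value, x$n_perm, x$difference_likelihood, x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.cvm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         difference_likelihood = x$difference_likelihood,
         n_perm = x$n_perm, n1 = x$n1, n2 = x$n2)
}

#' Classical two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] (two-sided, asymptotic p-value)
#' returning a tidy one-row tibble.
#'
#' @inheritParams cvm_two_sample
#' @return A tibble with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(s1, s2) {
  s1 <- event_amplitudes(s1)
  s2 <- event_amplitudes(s2)
  if (length(s1) < 5 || length(s2) < 5) {
    abort("each sample needs at least 5 observations")
  }
  kt <- suppressWarnings(ks.test(s1, s2, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
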