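#' @export
autoplot.effect_clusters <- function(object, ...) {
  if (object$degenerate) abort("degenerate clustering: nothing to plot")
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(.data$y_mean, .data$y_sd,
                               colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = object$centroids, shape = 4, size = 4,
                        stroke = 1.5) +
    ggplot2::labs(x = "blocker effect on mean (pre/post)",
                  y = "blocker effect on SD (pre/post)",
                  colour = NULL,
                  subtitle = sprintf("mean silhouette %.2f",
                                     object$mean_silhouette)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nsfa_fit <- function(object, ...) {
  ggplot2::ggplot(object$bin_points, ggplot2::aes(.data$I)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$variance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "mean current I (pA)",
                  y = expression(ensemble ~ variance ~ (pA^2)),
                  subtitle = sprintf("i = %.2f pA, N = %.1f, R = %.3f",
                                     object$i, object$N, object$R)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sim_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trace[c("time", "v_soma", "i_net")],
    -"time", names_to = "signal")
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$signal, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(v_soma = "somatic V (mV)",
                            i_net = "net synaptic current (nA)"))) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution-curve comparison plot
#'
#' Overlays amplitude distribution curves (e.g. pre, post and
#' reconstructed) on one grid.
#'
#' @param curves Named list of [distribution_curve()] tibbles.
#' @return A ggplot.
#' @export
plot_distribution_curves <- function(curves) {
  df <- dplyr::bind_rows(curves, .id = "curve")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$rel_freq,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "amplitude (pA)", y = "relative frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gain_protocol <- function(object, ...) {
  runs <- dplyr::semi_join(object$runs,
                           dplyr::filter(object$sets, .data$v_gate),
                           by = "set")
  df <- dplyr::bind_rows(
    dplyr::transmute(runs, set = .data$set, i_mean = .data$i_mean_pre,
                     spikes = .data$spikes_pre, state = "before"),
    dplyr::transmute(runs, set = .data$set, i_mean = .data$i_mean_pre,
                     spikes = .data$spikes_post, state = "after"))
  ggplot2::ggplot(df, ggplot2::aes(.data$i_mean, .data$spikes,
                                   colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "net synaptic current before amplification (nA)",
                  y = "spikes per window", colour = NULL) +
    ggplot2::theme_minimal()
}
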