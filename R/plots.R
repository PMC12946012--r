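#' @exportS3Method ggplot2::autoplot
autoplot.umap_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$umap1, .data$umap2)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_classic()
}

#' @exportS3Method ggplot2::autoplot
autoplot.interneuron_classification <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$umap1, .data$umap2,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_colour_manual(values = c(FS = "#E69F00",
                                            nonFS = "#2E8B57")) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL,
                  subtitle = sprintf("mean silhouette %.2f",
                                     attr(object, "mean_silhouette"))) +
    ggplot2::theme_classic()
}

#' Box plots of a feature by FS / non-FS group
#'
#' Mirrors the intrinsic-property comparison panels: one box per group over
#' individual cells.
#'
#' @param features raw feature tibble.
#' @param labels classification result (or `cell_id`/`label` tibble).
#' @param feature feature column to plot.
#' @return A ggplot object.
#' @export
plot_feature_comparison <- function(features, labels,
                                    feature = "ap_halfwidth") {
  lab <- labels$label[match(features$cell_id, labels$cell_id)]
  df <- tibble::tibble(label = lab, value = features[[feature]])
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c(FS = "#E69F00",
                                          nonFS = "#2E8B57"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_classic()
}

#' EPSC amplitude time course of one connection
#'
#' First-pulse amplitudes over experiment time, failures marked, epoch
#' shading from the wash-in time.
#'
#' @param events tibble from [measure_connection()].
#' @param onset_s optional wash-in time drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_connection_timecourse <- function(events, onset_s = NULL) {
  df <- events[events$pulse == 1L & events$valid, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude,
                                        colour = .data$is_failure)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "#D55E00"),
                                 labels = c("EPSC", "failure"),
                                 name = NULL) +
    ggplot2::labs(x = "time (s)", y = "EPSC amplitude (pA)") +
    ggplot2::theme_classic()
  if (!is.null(onset_s))
    p <- p + ggplot2::geom_vline(xintercept = onset_s, linetype = 2)
  p
}

#' Binned, baseline-subtracted holding-current time course
#'
#' @param course a [holding_course()] result (or its `bins`).
#' @return A ggplot object.
#' @export
plot_holding_course <- function(course) {
  bins <- if (is.data.frame(course)) course else course$bins
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin_center_s, .data$mean_pa,
                                     colour = .data$phase)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = 1), alpha = 0.5) +
    ggplot2::labs(x = "time from wash-in (s)",
                  y = expression(Delta * " holding current (pA)"),
                  colour = NULL) +
    ggplot2::theme_classic()
}
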