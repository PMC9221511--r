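# Thin ggplot2 views of the result objects.

#' Plot the SPM values of a fit
#'
#' Scatter of each gene's SPM per region with the permutation threshold tau
#' as a dashed line; specific calls are colored.
#'
#' @param object An `spm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spm_fit <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$region, y = .data$spm,
                                      colour = .data$is_specific)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$null_dist$threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(y = "SPM", x = NULL, colour = "specific") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null SPM distribution
#'
#' Histogram of the pooled null SPM values with the threshold tau marked.
#'
#' @param null_dist A `null_spm_distribution`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_null_spm <- function(null_dist, bins = 60) {
  df <- tibble(spm = null_dist$null_spms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spm)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = null_dist$threshold, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "null SPM", y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an interspecies expression comparison
#'
#' @param pairs Mapped pair tibble from [map_orthologs()].
#' @param x_lab,y_lab Axis labels (species names).
#' @return A ggplot object.
#' @export
plot_interspecies <- function(pairs, x_lab = "x species", y_lab = "y species") {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x_value, y = .data$y_value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::labs(x = x_lab, y = y_lab) +
    ggplot2::theme_minimal()
}

#' Heatmap of z-scored SPM values
#'
#' @param zspm Tibble from [zscore_spm()] (or an SPM profile set).
#' @return A ggplot object.
#' @export
plot_spm_heatmap <- function(zspm) {
  id <- names(zspm)[1]
  long <- zspm |>
    pivot_longer(-all_of(id), names_to = "column", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data[[id]],
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(SPM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
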