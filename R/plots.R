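#' Plot a droplet composition table
#'
#' Bar chart of the seven occupancy-category fractions, the visual
#' counterpart of comparing predicted and sorted compositions.
#'
#' @param object A `composition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$category <- factor(df$category, levels = composition_categories)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = NULL, y = "fraction of droplets",
      title = sprintf("Droplet composition (%s, %s)",
                      attr(object, "source"), attr(object, "conditioning"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Ranked-barcode (knee) plot
#'
#' Log-log plot of barcode total counts against rank, with the detected
#' knee marked when one is called.
#'
#' @param object A `ranked_barcodes` tibble from [rank_barcodes()].
#' @param knee Optional result of [detect_knee()] to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_barcodes <- function(object, knee = NULL, ...) {
  p <- ggplot2::ggplot(object[object$total > 0, ],
                       ggplot2::aes(x = .data$rank, y = .data$total)) +
    ggplot2::geom_line(linewidth = 0.6, colour = "#225ea8") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "total UMIs",
                  title = "Ranked-barcode plot") +
    ggplot2::theme_minimal()
  if (!is.null(knee) && !knee$no_inflection) {
    p <- p + ggplot2::geom_vline(xintercept = knee$knee_rank,
                                 linetype = "dashed", colour = "#d95f0e") +
      ggplot2::annotate("text", x = knee$knee_rank, y = max(object$total),
                        label = sprintf("knee = %d", knee$knee_rank),
                        hjust = -0.1, vjust = 1, size = 3)
  }
  p
}

#' Barnyard scatter plot
#'
#' Species-A versus species-B UMI counts per barcode, coloured by the
#' cross-species doublet call.
#'
#' @param object A `barnyard_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barnyard_stats <- function(object, ...) {
  df <- object$per_barcode[!is.na(object$per_barcode$purity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count_a, y = .data$count_b,
                                   colour = .data$is_cross_doublet)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#e31a1c"),
                                 name = "cross-species") +
    ggplot2::labs(x = "species A UMIs", y = "species B UMIs",
                  title = sprintf("Barnyard plot (observed cross rate %.1f%%)",
                                  100 * object$summary$observed_cross_rate)) +
    ggplot2::theme_minimal()
}

#' Nuclear-fraction QC plot
#'
#' Histogram of per-barcode nuclear fractions coloured by status call,
#' showing the empty / cell / damaged modes the classifier separates.
#'
#' @param object A `qc_report`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_report <- function(object, bins = 60, ...) {
  df <- object$per_barcode[!is.na(object$per_barcode$nuclear_fraction), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nuclear_fraction,
                                   fill = .data$status_call)) +
    ggplot2::geom_histogram(bins = bins, position = "stack") +
    ggplot2::scale_fill_manual(values = c(cell = "#238b45", empty = "grey60",
                                          damaged = "#cb181d")) +
    ggplot2::labs(x = "nuclear fraction (unspliced / total)", y = "barcodes",
                  fill = "status") +
    ggplot2::theme_minimal()
}
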