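#' Volcano plot of a differential-expression analysis
#'
#' Plots -log10 adjusted p against log2 fold change, coloring DEPs;
#' sentinel-coded proteins (no p-value) are omitted with a note in the
#' subtitle.
#'
#' @param object A `dep_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dep_analysis
#' @export
autoplot.dep_analysis <- function(object, ...) {
  tb <- dplyr::filter(object$table, .data$sentinel == "none",
                      !is.na(.data$adj_p_value))
  n_sent <- sum(object$table$sentinel != "none")
  ggplot2::ggplot(tb, ggplot2::aes(.data$log2_fc,
                                   -log10(.data$adj_p_value),
                                   colour = .data$dep)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      colour = "DEP",
      title = sprintf("%s vs %s", object$experimental, object$control),
      subtitle = if (n_sent > 0) {
        sprintf("%d sentinel-coded protein(s) not shown", n_sent)
      }
    ) +
    ggplot2::theme_minimal()
}

#' Paired flux plot of a flux comparison
#'
#' @param object A `flux_comparison`.
#' @param ... Unused.
#' @return A ggplot object (optimized vs dysregulated flux per reaction).
#' @method autoplot flux_comparison
#' @export
autoplot.flux_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$reactions,
                              c("flux_optimized", "flux_dysregulated"),
                              names_to = "condition", values_to = "flux",
                              names_prefix = "flux_")
  ggplot2::ggplot(long, ggplot2::aes(.data$reaction, .data$flux,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mol hr^-1 gDW^-1)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked-score plot of a weighted centrality ranking
#'
#' @param object A `target_ranking` from [weighted_rank()].
#' @param top_n How many top nodes to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot target_ranking
#' @export
autoplot.target_ranking <- function(object, top_n = 20, ...) {
  tb <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(tb, ggplot2::aes(stats::reorder(.data$node, .data$score),
                                   .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weighted centrality score") +
    ggplot2::theme_minimal()
}

#' Trace plot of an EEG screening result
#'
#' @param object An `eeg_screen`.
#' @param trace The [eeg_trace()] that was screened (the screen object
#'   keeps only summary metadata).
#' @param ... Unused.
#' @return A ggplot object with detected events shaded.
#' @method autoplot eeg_screen
#' @export
autoplot.eeg_screen <- function(object, trace, ...) {
  stopifnot(inherits(trace, "eeg_trace"))
  df <- tidy(trace)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "signal") +
    ggplot2::theme_minimal()
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$events,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2
    )
  }
  p
}
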