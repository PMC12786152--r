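#' Boxplot of tortuosity by vessel class
#'
#' Grouped boxplots of per-vessel tortuosity, optionally faceted by a
#' grouping column (e.g. dataset or condition). Requires ggplot2.
#'
#' @param records Tibble from [tortuosity_records()] (valid rows are used).
#' @param group Optional name of a column in `records` to facet by.
#' @return A ggplot object.
#' @export
plot_tortuosity <- function(records, group = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  rec <- records[records$valid & !is.na(records$t), , drop = FALSE]
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$vessel_class, y = .data$t,
                                         fill = .data$vessel_class)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(artery = "#d1495b", vein = "#30638e")) +
    ggplot2::labs(x = NULL, y = "Tortuosity (arc / chord)") +
    ggplot2::theme_minimal()
  if (!is.null(group) && group %in% names(rec)) {
    p <- p + ggplot2::facet_wrap(group)
  }
  p
}
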