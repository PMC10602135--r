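#' Plot transition frequencies
#'
#' Best-effort visual of the transition matrix: a source-by-destination
#' frequency heatmap (the tabular cousin of a chord diagram — ribbon width
#' there, tile shade here). Requires ggplot2.
#'
#' @param m A [transition_matrix()] or any labelled square count matrix.
#' @param path Optional SVG output path; `NULL` returns the ggplot object.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
plot_transition_frequencies <- function(m, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- tibble::as_tibble(as.table(unclass(m)), .name_repair = "minimal")
  names(df) <- c("from", "to", "count")
  df$from <- factor(df$from, levels = rev(rownames(m)))
  df$to <- factor(df$to, levels = colnames(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                        fill = .data$count)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c") +
    ggplot2::labs(x = "destination step", y = "source step",
                  fill = "transitions") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (is.null(path)) return(p)
  grDevices::svg(path, width = 7, height = 6)
  print(p)
  grDevices::dev.off()
  invisible(p)
}
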