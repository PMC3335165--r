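# ggplot2 views of the main result types. Figures are derived artifacts:
# everything they show comes from the tabular stage outputs.

#' Genome-wide gain/loss frequency plot
#'
#' Gains plotted upward and losses downward along genome order, with
#' chromosome boundaries marked.
#'
#' @param freq Output of [cna_frequency()] (with map columns attached).
#' @return A ggplot object.
#' @export
plot_frequency <- function(freq) {
  if (!all(c("chromosome", "position") %in% names(freq))) {
    abort("frequency table needs `chromosome` and `position`; pass `map` to cna_frequency()")
  }
  if (!nrow(freq)) {
    warn("empty frequency table; returning empty axes")
    return(ggplot2::ggplot() + ggplot2::theme_minimal())
  }
  freq$chromosome <- chrom_factor(freq$chromosome)
  freq <- freq[order(freq$chromosome, freq$position), ]
  freq$x <- seq_len(nrow(freq))
  bounds <- freq |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(at = max(.data$x) + 0.5)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$frac_gain), fill = "firebrick",
                      width = 1) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$frac_loss),
                      fill = "forestgreen", width = 1) +
    ggplot2::geom_vline(xintercept = head(bounds$at, -1),
                        colour = "purple", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "clones in genome order",
                  y = "fraction of samples (gain up, loss down)") +
    ggplot2::theme_minimal()
}

#' Per-sample aberration call heatmap
#'
#' @param calls Call table from [call_clones()].
#' @param map Clone map for genome ordering.
#' @return A ggplot object.
#' @export
plot_calls_heatmap <- function(calls, map) {
  long <- tidyr::pivot_longer(calls, -"probe_id",
                              names_to = "sample_id", values_to = "call")
  if (!nrow(long) || all(is.na(long$call))) {
    warn("empty call matrix; returning empty axes")
    return(ggplot2::ggplot() + ggplot2::theme_minimal())
  }
  map <- with_position(map)
  ord <- map$clone_id[order(chrom_factor(map$chromosome), map$position)]
  long$probe_id <- factor(long$probe_id, levels = ord)
  long$call <- factor(long$call, levels = CALL_LEVELS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$probe_id, y = .data$sample_id,
                                     fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(homdel = "darkgreen", loss = "palegreen", neutral = "white",
                 gain = "lightcoral", amp = "darkred"),
      na.value = "grey80", drop = FALSE) +
    ggplot2::labs(x = "clones in genome order", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn plot_frequency Heatmap of the binned diagonal correlation map.
#' @param object A `cna_binned_map`.
#' @param ... Unused.
#' @export
autoplot.cna_binned_map <- function(object, ...) {
  g <- object$grid
  g$expr_bin <- factor(g$expr_bin, levels = unique(g$expr_bin))
  g$cn_bin <- factor(g$cn_bin, levels = levels(g$expr_bin))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$cn_bin, y = .data$expr_bin,
                                  fill = .data$mean_r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "copy-number bin", y = "expression bin",
                  fill = "mean r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Copy-number profile of one sample with its segmentation
#'
#' @param ratios Raw ratio table.
#' @param segmentation A `cna_segmentation`.
#' @param sample_id Sample to plot.
#' @param map Clone map.
#' @return A ggplot object.
#' @export
plot_profile <- function(ratios, segmentation, sample_id, map) {
  map <- with_position(map)
  m <- ratio_matrix(ratios)
  if (!sample_id %in% colnames(m)) abort("unknown sample id")
  df <- tibble::tibble(
    probe_id = rownames(m),
    value = m[, sample_id]
  ) |>
    dplyr::left_join(map[, c("clone_id", "chromosome", "position")],
                     by = c(probe_id = "clone_id"))
  df$chromosome <- chrom_factor(df$chromosome)
  df <- df[order(df$chromosome, df$position), ]
  df$x <- seq_len(nrow(df))
  segs <- segmentation$segments[segmentation$segments$sample_id == sample_id, ]
  offs <- cumsum(c(0, head(as.vector(table(df$chromosome)), -1)))
  names(offs) <- levels(df$chromosome)
  segs$x1 <- offs[as.character(segs$chromosome)] + segs$start_index
  segs$x2 <- offs[as.character(segs$chromosome)] + segs$end_index - 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x1, xend = .data$x2,
                                       y = .data$mean, yend = .data$mean),
                          colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "clones in genome order", y = "log2 ratio",
                  title = sample_id) +
    ggplot2::theme_minimal()
}
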