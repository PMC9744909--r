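# ggplot2 display methods. Figures are decorative; every plotted quantity is
# also written as a numeric table elsewhere in the package.

#' Heatmap of an anchored (log2 ratio) matrix
#'
#' Rows in matrix order (top = first row), symmetric diverging colour scale
#' centred at 0.
#'
#' @param object An `anchored_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.anchored_matrix <- function(object, ...) {
  df <- tidy(object)
  df$gene_id <- factor(df$gene_id, levels = rev(rownames(object)))
  lim <- max(abs(df$value), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$gene_id,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "position relative to +1 dyad (bp)", y = NULL,
                  fill = attr(object, "label") %||% "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Occupancy track segment
#'
#' @param object An `occupancy_track`.
#' @param chrom Chromosome to show (default first).
#' @param from,to 0-based range to show (default whole chromosome).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.occupancy_track <- function(object, chrom = names(object$score)[1],
                                     from = 0L,
                                     to = object$chrom_lengths[[chrom]] - 1L,
                                     ...) {
  pos <- seq(from, to)
  df <- tibble(pos = pos, score = object$score[[chrom]][pos + 1L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "normalized occupancy") +
    ggplot2::theme_minimal()
}

#' Average occupancy profile curves
#'
#' @param profile A tibble from [average_profile()].
#' @param window Optional pair of offsets to shade (e.g. the scored NDR
#'   window `c(-150, -50)`).
#' @return A ggplot.
#' @export
plot_profile <- function(profile, window = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$occupancy,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to +1 dyad (bp)",
                  y = "mean normalized occupancy", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}
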