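#' Plot methods
#'
#' `autoplot()` methods for the package's tabular result types: linked-SNP
#' density tracks, windowed LD tracks, per-gene clade patterns, and
#' expression Z-score heatmaps.
#'
#' @param object a result object from the corresponding function.
#' @param ... unused.
#' @return a [ggplot2::ggplot].
#' @name sdr-plots
NULL

#' @rdname sdr-plots
#' @export
autoplot.sdr_density_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$per_kbp,
                               fill = .data$linked_class)) +
    ggplot2::geom_col(width = attr(object, "window_bp")) +
    ggplot2::facet_wrap(~linked_class, ncol = 1) +
    ggplot2::labs(x = "position on reference (bp)",
                  y = "sex-linked SNPs per kbp", fill = "linked class") +
    ggplot2::theme_minimal()
}

#' @rdname sdr-plots
#' @export
autoplot.sdr_ld_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$median_r2)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)",
                  y = expression("median " * r^2 * " per window")) +
    ggplot2::theme_minimal()
}

#' @rdname sdr-plots
#' @export
autoplot.sdr_clade_patterns <- function(object, ...) {
  d <- as_tibble(object)
  d$gene_id <- factor(d$gene_id, levels = d$gene_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id, y = 1,
                                  fill = .data$verdict)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(M_separated = "#7b3294",
                                          F_separated = "#e6b800",
                                          none = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "exclusive clade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname sdr-plots
#' @export
autoplot.sdr_zscore <- function(object, ...) {
  z <- unclass(object)
  attr(z, "constant") <- NULL; attr(z, "design") <- NULL
  d <- as_tibble(as.data.frame.table(z, stringsAsFactors = FALSE))
  names(d) <- c("gene", "sample", "z")
  d$gene <- factor(d$gene, levels = rev(rownames(object)))
  d$sample <- factor(d$sample, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$gene,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
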