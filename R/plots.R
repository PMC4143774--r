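# ggplot2 displays for the result types.

#' Plot a rank comparison for combined evidence
#'
#' Association-only rank against combined rank, log-log, with the diagonal;
#' genes below the diagonal were promoted by the linkage evidence.
#'
#' @param object A `la_combined` object from [combine_genes()].
#' @param k Highlight threshold drawn as reference lines; default 49.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot la_combined
#' @export
autoplot.la_combined <- function(object, k = 49, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rank_assoc, y = .data$rank_combined)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_hline(yintercept = k, linetype = 3, colour = "grey40") +
    ggplot2::geom_vline(xintercept = k, linetype = 3, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Association-only rank", y = "Combined rank") +
    ggplot2::theme_minimal()
}

#' Plot a power report
#'
#' Side-by-side top-K detection power of the association-only and combined
#' rankings, per causal gene (and trait, when present).
#'
#' @param object A `la_power` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot la_power
#' @export
autoplot.la_power <- function(object, ...) {
  df <- glance(object) |>
    tidyr::pivot_longer(c("power_assoc", "power_combined"),
                        names_to = "method", values_to = "power",
                        names_prefix = "power_")
  if ("trait" %in% names(df)) {
    df$gene_id <- paste(df$gene_id, df$trait, sep = " / ")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$power,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = sprintf("Top-%d detection power", object$k[1]),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot linkage tracks with gene intervals
#'
#' LOD against genetic position, one panel per chromosome, with optional
#' gene cM intervals drawn along the axis.
#'
#' @param tracks Linkage tracks (`chrom`, `pos_cm`, `lod`).
#' @param genes Optional gene table that already has `cm_start`/`cm_end`
#'   (e.g. from [gene_linkage_table()]).
#' @return A ggplot object.
#' @export
plot_lod_tracks <- function(tracks, genes = NULL) {
  tracks <- validate_tracks(tracks)
  p <- ggplot2::ggplot(tracks, ggplot2::aes(x = .data$pos_cm, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Genetic position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(genes) && all(c("cm_start", "cm_end") %in% names(genes))) {
    p <- p + ggplot2::geom_segment(
      data = genes,
      ggplot2::aes(x = .data$cm_start, xend = .data$cm_end, y = 0, yend = 0),
      colour = "red", linewidth = 2, inherit.aes = FALSE
    )
  }
  p
}
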