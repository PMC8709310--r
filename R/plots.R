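#' Segment map of an annotated protein panel
#'
#' Draws each protein as a horizontal backbone with its conserved segments
#' colored by type — the classic dehydrin architecture cartoon.
#'
#' @param annotation Output of [annotate_panel()].
#' @param lengths Optional named vector of protein lengths (otherwise the
#'   backbone runs to the last hit).
#' @return A ggplot object.
#' @export
plot_segment_map <- function(annotation, lengths = NULL) {
  hits <- annotation |>
    dplyr::select("protein_id", "hits") |>
    tidyr::unnest("hits")
  ends <- hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop")
  if (!is.null(lengths)) {
    ends$len <- pmax(ends$len, lengths[ends$protein_id])
  }
  ggplot2::ggplot(hits) +
    ggplot2::geom_segment(
      data = ends,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$protein_id, yend = .data$protein_id),
      linewidth = 0.4, colour = "grey60"
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$protein_id, yend = .data$protein_id,
        colour = .data$segment_type
      ),
      linewidth = 4
    ) +
    ggplot2::labs(x = "residue", y = NULL, colour = "segment") +
    ggplot2::theme_minimal()
}

#' Drought-induced percent change per gene
#'
#' @param pc Output of [percent_change()].
#' @return A ggplot object.
#' @export
plot_percent_change <- function(pc) {
  ggplot2::ggplot(pc, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$percent_change),
    y = .data$percent_change
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "drought-induced change (%)") +
    ggplot2::theme_minimal()
}

#' Climate-niche classes along the first principal component
#'
#' @param niche Output of [climate_pc1_classes()].
#' @param cutoff Class cutoffs drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_niche_classes <- function(niche, cutoff = 2.5) {
  ggplot2::ggplot(niche, ggplot2::aes(
    x = .data$pc1_score,
    y = stats::reorder(.data$ecotype, .data$pc1_score),
    colour = .data$class
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-cutoff, cutoff), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(cold = "#3366cc", mesic = "grey40", warm = "#cc3333")
    ) +
    ggplot2::labs(x = "climate PC1 score", y = NULL, colour = "class") +
    ggplot2::theme_minimal()
}
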