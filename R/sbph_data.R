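#' Published regulation patterns of the SBPH candidate pathways
#'
#' The per-contrast direction calls of the 25 rice metabolic pathways
#' nominated in the SBPH infestation study as resistance- or
#' susceptibility-associated (the two genotype-opposing pathways, ureide
#' biosynthesis and phenylalanine degradation III, carry both labels).
#' Temporal contrasts use up/down, genotype contrasts higher/lower; a
#' blank cell means the pathway was not differentially regulated in that
#' contrast.  The reported class labels ride along for cross-checking;
#' [classify_pathways()] re-derives them from the direction columns alone.
#'
#' @param keep_reported if `TRUE`, attach the reported class labels as the
#'   attributes `reported_resistance_class` / `reported_susceptibility_class`
#'   (aligned with rows).
#' @return a `regulation_patterns` tibble of 25 pathways.
#' @examples
#' glance(classify_pathways(sbph_patterns()))
#' @export
sbph_patterns <- function(keep_reported = FALSE) {
  path <- system.file("extdata", "sbph_pathway_patterns.tsv",
                      package = "pathcontrast", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  pat <- as_regulation_patterns(
    dplyr::select(df, "pathway_id", dplyr::all_of(contrast_labels()))
  )
  if (keep_reported) {
    attr(pat, "reported_resistance_class") <- df$reported_resistance_class
    attr(pat, "reported_susceptibility_class") <- df$reported_susceptibility_class
  }
  pat
}

#' Bar chart of a four-contrast Venn partition
#'
#' The 15 Venn categories as a bar chart ordered by subset size — a
#' faithful tabular rendering of the information in a four-set Venn
#' diagram without the geometry.
#'
#' @param object a `venn_partition` from [venn_partition()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.venn_partition <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    size = stringr::str_count(.data$category, stringr::fixed("+")) + 1,
    category = factor(.data$category, levels = venn_categories())
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = factor(.data$size))) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "contrasts in subset") +
    ggplot2::labs(x = "contrast subset", y = "differentially regulated pathways") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tile map of classified regulation patterns
#'
#' One row per classed pathway, one column per contrast, tiles coloured by
#' call direction and faceted by resistance class — the standard way to
#' eyeball whether the class rules carved the pattern space as intended.
#'
#' @param object a `pathway_classification` from [classify_pathways()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pathway_classification <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$resistance_class != "none" |
                    .data$susceptibility_class != "none") |>
    dplyr::mutate(class = dplyr::if_else(
      .data$resistance_class != "none",
      paste("resistance", .data$resistance_class),
      paste("susceptibility", .data$susceptibility_class)
    )) |>
    tidyr::pivot_longer(dplyr::all_of(contrast_labels()),
                        names_to = "contrast", values_to = "direction") |>
    dplyr::mutate(contrast = factor(.data$contrast, levels = contrast_labels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$pathway_id,
                                   fill = .data$direction)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(up = "#b2182b", down = "#2166ac", mixed = "#998ec3"),
      na.value = "grey95", name = "call"
    ) +
    ggplot2::labs(x = NULL, y = NULL)
}
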