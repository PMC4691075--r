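#' Percent change of a concentration
#'
#' `100 * (after - before) / before`, rounded to one decimal with ties
#' going half away from zero (so 895.65 -> 895.7 and -46.965 -> -47.0,
#' matching how the published concentration table rounds).
#'
#' @param before,after positive concentrations (vectorised; `before` must
#'   be > 0).
#' @return percent change, one decimal.
#' @examples
#' percent_change(443.7, 235.3)  # -47.0
#' percent_change(2.3, 22.9)     # 895.7
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) {
    rlang::abort("percent_change: 'before' concentrations must be > 0")
  }
  round_half_away(100 * (after - before) / before, 1)
}

# round-half-away-from-zero at `digits` decimals (base round() is banker's);
# the inner 6-dp round keeps binary representation error from pushing an
# exact .5 tie below the cut
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(round(abs(x) * m, 6) + 0.5) / m
}

#' Free amino-acid concentrations in resistant and susceptible rice
#'
#' The packaged measurements of 25 free amino acids (plus their total),
#' in ug per g fresh weight, in the susceptible (S) and resistant (R) rice
#' lines before (0 h) and after (6 h) planthopper infestation, as reported
#' in the SBPH infestation study: per-condition means with standard errors
#' of three replicates and the percent-change columns as printed there.
#'
#' @param source optional path to an alternative TSV with the same layout.
#' @return tibble with columns `analyte`, `<cond>_mean` / `<cond>_se` for
#'   conditions S0, R0, S6, R6, and `printed_change_S6_S0` /
#'   `printed_change_R6_R0`.
#' @export
amino_acid_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "amino_acids.tsv",
                          package = "pathcontrast", mustWork = TRUE)
  }
  df <- readr::read_tsv(source, show_col_types = FALSE, progress = FALSE)
  num <- setdiff(names(df), "analyte")
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(num), as.numeric))
  means <- paste0(c("S0", "R0", "S6", "R6"), "_mean")
  stopifnot(all(means %in% names(df)))
  if (any(as.matrix(df[means]) <= 0)) {
    rlang::abort("amino_acid_table: concentrations must be positive")
  }
  tibble::as_tibble(df)
}

#' Recompute the percent-change columns of an amino-acid table
#'
#' For each analyte, the 6 h vs 0 h percent change of concentration within
#' each genotype is recomputed from the concentration columns
#' (`S6_S0` from S0/S6, `R6_R0` from R0/R6).  Where the table carries
#' printed change columns, recomputed and printed values are placed side by
#' side and rows whose printed value disagrees with the recomputation by
#' more than 0.05 (in either genotype) are flagged rather than reconciled.
#' If a `Total` row is present, the total is additionally recomputed as the
#' sum of the individual analytes (`recomputed_*_from_sum`).
#'
#' @param table tibble from [amino_acid_table()].
#' @return an `aa_changes` tibble: `analyte`, recomputed changes, printed
#'   changes (if available), `discrepant` flag, and per-genotype increase
#'   ranks (`rank_R`, `rank_S`; rank 1 = largest signed increase among
#'   individual analytes).
#' @examples
#' table_changes(amino_acid_table())
#' @export
table_changes <- function(table) {
  out <- table |>
    dplyr::mutate(
      recomputed_S6_S0 = percent_change(.data$S0_mean, .data$S6_mean),
      recomputed_R6_R0 = percent_change(.data$R0_mean, .data$R6_mean)
    )
  has_printed <- all(c("printed_change_S6_S0", "printed_change_R6_R0") %in% names(out))
  if (has_printed) {
    out <- dplyr::mutate(
      out,
      discrepant = abs(.data$recomputed_S6_S0 - .data$printed_change_S6_S0) > 0.05 |
        abs(.data$recomputed_R6_R0 - .data$printed_change_R6_R0) > 0.05
    )
  } else {
    out$discrepant <- FALSE
  }

  is_total <- out$analyte == "Total"
  if (any(is_total)) {
    rows <- !is_total
    out$recomputed_S6_S0_from_sum <- NA_real_
    out$recomputed_R6_R0_from_sum <- NA_real_
    out$recomputed_S6_S0_from_sum[is_total] <-
      percent_change(sum(out$S0_mean[rows]), sum(out$S6_mean[rows]))
    out$recomputed_R6_R0_from_sum[is_total] <-
      percent_change(sum(out$R0_mean[rows]), sum(out$R6_mean[rows]))
  }

  # increase rankings over individual analytes (Total excluded)
  out$rank_S <- out$rank_R <- NA_integer_
  out$rank_S[!is_total] <- rank(-out$recomputed_S6_S0[!is_total],
                                ties.method = "min")
  out$rank_R[!is_total] <- rank(-out$recomputed_R6_R0[!is_total],
                                ties.method = "min")

  cols <- c("analyte", "recomputed_S6_S0", "recomputed_R6_R0",
            intersect(c("printed_change_S6_S0", "printed_change_R6_R0"), names(out)),
            "discrepant",
            intersect(c("recomputed_S6_S0_from_sum", "recomputed_R6_R0_from_sum"),
                      names(out)),
            "rank_S", "rank_R")
  out <- dplyr::select(out, dplyr::all_of(cols))
  structure(out, class = c("aa_changes", class(tibble::tibble())))
}

#' Plot recomputed amino-acid percent changes
#'
#' Diverging bar chart of the recomputed 6 h vs 0 h percent changes per
#' genotype; discrepant rows (printed change inconsistent with the printed
#' concentrations) are outlined.
#'
#' @param object an `aa_changes` tibble from [table_changes()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aa_changes <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$analyte != "Total") |>
    tidyr::pivot_longer(c("recomputed_S6_S0", "recomputed_R6_R0"),
                        names_to = "genotype", values_to = "change") |>
    dplyr::mutate(genotype = dplyr::if_else(
      .data$genotype == "recomputed_R6_R0", "resistant (R6 vs R0)",
      "susceptible (S6 vs S0)"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$change,
    y = stats::reorder(.data$analyte, .data$change),
    fill = .data$change > 0, colour = .data$discrepant
  )) +
    ggplot2::geom_col(linewidth = 0.6) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac"),
                               guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 na.translate = FALSE, name = "flagged") +
    ggplot2::labs(x = "percent change of concentration (6 h vs 0 h)",
                  y = NULL)
}
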