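#' Read a per-contrast differential-expression table
#'
#' One TSV per contrast with header `gene_id	fold_change	q_value` or
#' `gene_id	log2fc	q_value`; an optional `contrast` column may carry the
#' label instead of the `contrast` argument.  Fold changes are
#' canonicalised to positive ratios (log2 input `x` becomes `2^x`), with
#' the first-named condition of the contrast label as numerator.
#'
#' @param source path to a TSV file or an equivalent data frame.
#' @param contrast contrast label for the whole file; required unless the
#'   table has a `contrast` column.
#' @return tibble with columns `contrast`, `gene_id`, `fold_change`
#'   (positive ratio), `q_value`.
#' @examples
#' df <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1, -2),
#'                  q_value = c(0.01, 0.2))
#' read_de_table(df, contrast = "R6_R0")
#' @export
read_de_table <- function(source, contrast = NULL) {
  df <- read_tsv_checked(source, required = c("gene_id", "q_value"),
                         what = "DE table")
  has_ratio <- "fold_change" %in% names(df)
  has_log2 <- "log2fc" %in% names(df)
  if (!has_ratio && !has_log2) {
    abort_format("DE table: need a fold_change or log2fc column")
  }
  if (has_ratio && has_log2) {
    abort_format("DE table: fold_change and log2fc are mutually exclusive")
  }

  if ("contrast" %in% names(df)) {
    df$contrast <- trimws(as.character(df$contrast))
  } else {
    if (is.null(contrast)) {
      abort_format("DE table: no contrast column and no contrast= argument")
    }
    df$contrast <- contrast
  }
  bad_contrast <- !df$contrast %in% contrast_labels()
  if (any(bad_contrast)) {
    abort_format(sprintf(
      "DE table: unknown contrast label %s at data row %d",
      df$contrast[which(bad_contrast)[1]], which(bad_contrast)[1]
    ))
  }

  fc_col <- if (has_ratio) "fold_change" else "log2fc"
  fc <- suppressWarnings(as.numeric(df[[fc_col]]))
  q <- suppressWarnings(as.numeric(df$q_value))
  if (any(is.na(fc))) {
    abort_format(sprintf("DE table: non-numeric %s at data row %d",
                         fc_col, which(is.na(fc))[1]))
  }
  if (has_log2) fc <- 2^fc
  if (any(fc <= 0)) {
    abort_format(sprintf("DE table: fold_change must be positive at data row %d",
                         which(fc <= 0)[1]))
  }
  if (any(is.na(q) | q < 0 | q > 1)) {
    abort_format(sprintf("DE table: q_value outside [0, 1] at data row %d",
                         which(is.na(q) | q < 0 | q > 1)[1]))
  }

  tibble::tibble(
    contrast = df$contrast,
    gene_id = trimws(as.character(df$gene_id)),
    fold_change = fc,
    q_value = q
  )
}

#' Filter DE records to the significant set and annotate direction
#'
#' The significance rule of the upstream microarray analysis: a gene is
#' differentially expressed when its fold-change ratio is >= 2 (up) or
#' <= 1/2 (down) and its q-value is < 0.05.  Both fold-change bounds are
#' inclusive (the down bound mirrors the "inverse of 2" colouring cutoff);
#' the q bound is strict.
#'
#' @param records tibble from [read_de_table()].
#' @param fc_threshold fold-change ratio threshold (default 2).
#' @param q_threshold q-value threshold (default 0.05, strict).
#' @return the significant subset with an added `direction` column
#'   (`"up"`/`"down"`).  Idempotent: filtering an already-filtered set is a
#'   no-op.
#' @examples
#' df <- data.frame(gene_id = c("a", "b", "c"),
#'                  fold_change = c(2.0, 1.99, 0.4),
#'                  q_value = c(0.049, 0.001, 0.05))
#' filter_significant(read_de_table(df, "R6_R0"))
#' @export
filter_significant <- function(records, fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(fc_threshold > 1, q_threshold > 0)
  records |>
    dplyr::filter(
      (.data$fold_change >= fc_threshold |
         .data$fold_change <= 1 / fc_threshold),
      .data$q_value < q_threshold
    ) |>
    dplyr::mutate(
      direction = dplyr::if_else(.data$fold_change >= fc_threshold, "up", "down")
    )
}
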