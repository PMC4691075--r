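#' Call pathway-level regulation for one contrast
#'
#' Maps significant, locus-keyed DE records onto the pathway database and
#' aggregates gene directions into one call per pathway: a pathway is
#' called as soon as at least one significant gene maps to it; the call is
#' `up` if every piece of evidence is up, `down` if every piece is down,
#' and `mixed` otherwise.  A locus observed through several probes with
#' conflicting directions contributes both directions (the pathway becomes
#' mixed): evidence is preserved, never averaged.
#'
#' @param significant_records tibble from [filter_significant()], keyed by
#'   locus (translate probes first with [translate_probes()]); all rows
#'   must belong to `contrast`.
#' @param db a `pathway_db`.
#' @param contrast the contrast label being called.
#' @return tibble with one row per called pathway: `pathway_id`,
#'   `contrast`, `direction` (`up`/`down`/`mixed`), `n_genes` (distinct
#'   significant loci), and `evidence` (list column of per-locus direction
#'   tibbles).  Output is independent of input row order.
#' @examples
#' db <- pathway_db(tibble::tibble(
#'   pathway_id = "P1", pathway_name = "toy", class_path = "Biosynthesis",
#'   genes = list(c("L1", "L2"))
#' ))
#' de <- tibble::tibble(contrast = "R6_R0", gene_id = c("L1", "L2"),
#'                      fold_change = c(2.5, 3.1), q_value = 0.01)
#' call_pathways(filter_significant(de), db, "R6_R0")
#' @export
call_pathways <- function(significant_records, db, contrast) {
  assert_contrast(contrast)
  recs <- dplyr::filter(significant_records, .data$contrast == !!contrast)
  if (nrow(recs) == 0) {
    return(tibble::tibble(pathway_id = character(), contrast = character(),
                          direction = character(), n_genes = integer(),
                          evidence = list()))
  }
  idx <- locus_index(db)
  mapped <- dplyr::inner_join(
    dplyr::select(recs, locus_id = "gene_id", "direction"),
    idx, by = "locus_id", relationship = "many-to-many"
  )
  mapped |>
    dplyr::distinct(.data$pathway_id, .data$locus_id, .data$direction) |>
    dplyr::arrange(.data$pathway_id, .data$locus_id, .data$direction) |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      evidence = list(tibble::tibble(locus_id = locus_id,
                                     direction = direction)),
      direction = aggregate_directions(.data$direction),
      n_genes = dplyr::n_distinct(.data$locus_id),
      .groups = "drop"
    ) |>
    dplyr::select("pathway_id", "direction", "n_genes", "evidence") |>
    dplyr::mutate(contrast = !!contrast, .after = "pathway_id")
}

# all-up -> up, all-down -> down, otherwise mixed
aggregate_directions <- function(direction) {
  u <- unique(direction)
  if (identical(u, "up")) "up" else if (identical(u, "down")) "down" else "mixed"
}

#' Assemble per-pathway regulation patterns across the four contrasts
#'
#' Binds pathway calls from up to four contrasts into one row per pathway
#' with a direction column per contrast (NA = not differentially regulated
#' in that contrast).  This wide table is the classifier input and matches
#' the published result-table layout.
#'
#' @param calls a tibble of pathway calls (rows from [call_pathways()],
#'   possibly concatenated across contrasts), or a list of such tibbles.
#' @return a `regulation_patterns` tibble: `pathway_id` plus the four
#'   direction columns `S6_S0`, `R6_R0`, `R0_S0`, `R6_S6` in canonical
#'   order.
#' @export
build_patterns <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- dplyr::bind_rows(calls)
  }
  if (nrow(calls) == 0) {
    out <- tibble::tibble(pathway_id = character())
    for (ct in contrast_labels()) out[[ct]] <- character()
    return(new_regulation_patterns(out))
  }
  assert_contrast(calls$contrast)
  dup <- calls |>
    dplyr::count(.data$pathway_id, .data$contrast) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_consistency(sprintf(
      "duplicate call(s) for the same (pathway, contrast): %s",
      paste(sprintf("(%s, %s)", dup$pathway_id, dup$contrast), collapse = ", ")
    ))
  }
  wide <- calls |>
    dplyr::select("pathway_id", "contrast", "direction") |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "direction")
  for (ct in setdiff(contrast_labels(), names(wide))) {
    wide[[ct]] <- NA_character_
  }
  out <- wide |>
    dplyr::select("pathway_id", dplyr::all_of(contrast_labels())) |>
    dplyr::arrange(.data$pathway_id)
  new_regulation_patterns(out)
}

new_regulation_patterns <- function(x) {
  structure(x, class = c("regulation_patterns", class(tibble::tibble())))
}

#' Build a patterns table directly from per-contrast directions
#'
#' Convenience constructor used for curated or simulated pattern tables;
#' accepts either canonical (`up`/`down`/`mixed`) or display
#' (`higher`/`lower`/`higher/lower`) vocabulary and empty strings for
#' absent calls.
#'
#' @param df data frame with `pathway_id` and any subset of the four
#'   contrast columns.
#' @return a `regulation_patterns` tibble in canonical vocabulary.
#' @export
as_regulation_patterns <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot("pathway_id" %in% names(df))
  if (anyDuplicated(df$pathway_id)) {
    abort_consistency("as_regulation_patterns: duplicate pathway_id rows")
  }
  for (ct in contrast_labels()) {
    df[[ct]] <- if (ct %in% names(df)) parse_direction(df[[ct]]) else NA_character_
  }
  out <- dplyr::select(df, "pathway_id", dplyr::all_of(contrast_labels()))
  new_regulation_patterns(out)
}

#' Render a patterns table in the published display vocabulary
#'
#' @param patterns a `regulation_patterns` tibble.
#' @return tibble with genotype-contrast columns rendered as
#'   higher/lower/"higher/lower" and absences as empty strings.
#' @export
format_patterns <- function(patterns) {
  out <- tibble::as_tibble(patterns)
  for (ct in contrast_labels()) {
    disp <- render_direction(out[[ct]], rep(ct, nrow(out)))
    out[[ct]] <- dplyr::coalesce(disp, "")
  }
  out
}

#' Tabulate called pathways by category and contrast
#'
#' Counts, for each contrast, the pathways with a call, grouped by the
#' category label at the requested depth of the class hierarchy (level 1 =
#' root, e.g. "Biosynthesis"; level 2 = subclass, e.g. "Amino acids
#' biosynthesis").  A pathway whose class path is shallower than `level` is
#' grouped at its deepest available label.  A pathway counts once per
#' contrast it is called in.
#'
#' @param patterns a `regulation_patterns` tibble.
#' @param db a `pathway_db` containing every pathway in `patterns`.
#' @param level hierarchy depth (default 2).
#' @return tibble `category` plus one count column per contrast, sorted by
#'   total count descending.
#' @export
tabulate_by_category <- function(patterns, db, level = 2) {
  stopifnot(level >= 1)
  missing <- setdiff(patterns$pathway_id, db$pathway_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("pathway(s) absent from database: %s",
                         paste(missing, collapse = ", ")))
  }
  cat_of <- function(class_path) {
    parts <- strsplit(class_path, "|", fixed = TRUE)[[1]]
    parts[min(level, length(parts))]
  }
  cats <- db |>
    tibble::as_tibble() |>
    dplyr::mutate(category = purrr::map_chr(.data$class_path, cat_of)) |>
    dplyr::select("pathway_id", "category")

  long <- patterns |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(contrast_labels()),
                        names_to = "contrast", values_to = "direction") |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::left_join(cats, by = "pathway_id")

  counts <- long |>
    dplyr::count(.data$category, .data$contrast) |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "n",
                       values_fill = 0L)
  for (ct in setdiff(contrast_labels(), names(counts))) counts[[ct]] <- 0L
  counts |>
    dplyr::select("category", dplyr::all_of(contrast_labels())) |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::all_of(contrast_labels())))) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$category) |>
    dplyr::select(-"total")
}

#' Shared and unique purely-regulated pathways between the temporal contrasts
#'
#' Intersects the sets of purely up- and purely down-regulated pathways in
#' the resistant (R6_R0) and susceptible (S6_S0) temporal responses.  Mixed
#' ("up/down") pathways belong to neither the up nor the down set.
#'
#' @param patterns a `regulation_patterns` tibble.
#' @return tibble with one row per direction (`up`, `down`): `shared`,
#'   `unique_R6_R0`, `unique_S6_S0` counts.
#' @examples
#' p <- as_regulation_patterns(tibble::tibble(
#'   pathway_id = c("a", "b", "c"),
#'   R6_R0 = c("up", "up", NA), S6_S0 = c("up", NA, "up")
#' ))
#' shared_unique_counts(p)  # shared 1, unique 1 and 1
#' @export
shared_unique_counts <- function(patterns) {
  sets <- function(contrast, dir) {
    patterns$pathway_id[!is.na(patterns[[contrast]]) & patterns[[contrast]] == dir]
  }
  purrr::map_dfr(c("up", "down"), function(dir) {
    r <- sets("R6_R0", dir)
    s <- sets("S6_S0", dir)
    tibble::tibble(
      direction = dir,
      shared = length(intersect(r, s)),
      unique_R6_R0 = length(setdiff(r, s)),
      unique_S6_S0 = length(setdiff(s, r))
    )
  })
}
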