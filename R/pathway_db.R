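#' Read a pathway--gene association table
#'
#' The pathway database is a flat, diff-able TSV in the style of a BioCyc
#' dump: one row per (pathway, gene) link with the category hierarchy
#' pipe-joined in one column.  Columns: `pathway_id`, `pathway_name`,
#' `class_path`, `gene_id`.  A row with an empty `gene_id` declares a
#' pathway with no (known) member genes; such pathways can never be called
#' differentially regulated but are retained so category tabulations see
#' them.
#'
#' @param source path to a TSV file, or a data frame already in the long
#'   (one row per link) layout.
#' @return a `pathway_db` tibble: one row per pathway with columns
#'   `pathway_id`, `pathway_name`, `class_path` (character, levels joined by
#'   `|`), and `genes` (list column of character vectors, possibly empty).
#'   Duplicate (pathway, gene) rows are deduplicated.
#' @details A `pathway_id` repeated with a conflicting name or class path is
#'   a consistency error: the database no longer identifies pathways
#'   uniquely.  Gene identifiers are opaque, case-sensitive strings.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "pathway_id\tpathway_name\tclass_path\tgene_id",
#'   "PWY1\tserine biosynthesis\tBiosynthesis|Amino acids biosynthesis\tLOC1",
#'   "PWY1\tserine biosynthesis\tBiosynthesis|Amino acids biosynthesis\tLOC2"
#' ), tf)
#' read_pathway_table(tf)
#' @export
read_pathway_table <- function(source) {
  long <- read_tsv_checked(
    source,
    required = c("pathway_id", "pathway_name", "class_path", "gene_id"),
    what = "pathway table"
  )
  long <- dplyr::mutate(
    long,
    dplyr::across(c("pathway_id", "pathway_name", "class_path", "gene_id"),
                  ~ trimws(as.character(.x)))
  )
  if (any(is.na(long$pathway_id) | long$pathway_id == "")) {
    bad <- which(is.na(long$pathway_id) | long$pathway_id == "")[1]
    abort_format(sprintf("pathway table: empty pathway_id at data row %d", bad))
  }
  if (any(is.na(long$class_path) | long$class_path == "")) {
    bad <- which(is.na(long$class_path) | long$class_path == "")[1]
    abort_format(sprintf(
      "pathway table: class_path must have at least one level (data row %d)", bad
    ))
  }

  meta <- dplyr::distinct(long, .data$pathway_id, .data$pathway_name, .data$class_path)
  dup <- meta$pathway_id[duplicated(meta$pathway_id)]
  if (length(dup) > 0) {
    abort_consistency(sprintf(
      "pathway table: pathway_id %s appears with conflicting name/class_path",
      paste(unique(dup), collapse = ", ")
    ))
  }

  db <- long |>
    dplyr::mutate(gene_id = dplyr::if_else(is.na(.data$gene_id), "", .data$gene_id)) |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name, .data$class_path) |>
    dplyr::summarise(
      genes = list(sort(unique(.data$gene_id[.data$gene_id != ""]))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$pathway_id)
  new_pathway_db(db)
}

new_pathway_db <- function(db) {
  structure(db, class = c("pathway_db", class(tibble::tibble())))
}

#' Construct a pathway database from a tibble
#'
#' Convenience constructor for in-memory databases (tests, simulations).
#'
#' @param pathways tibble with `pathway_id`, `pathway_name`, `class_path`
#'   and either a `genes` list column or a long `gene_id` column.
#' @return a `pathway_db` tibble (see [read_pathway_table()]).
#' @export
pathway_db <- function(pathways) {
  if ("genes" %in% names(pathways)) {
    df <- tidyr::unnest(
      dplyr::mutate(pathways, genes = purrr::map(.data$genes, ~ {
        g <- as.character(.x)
        if (length(g) == 0) "" else g
      })),
      "genes"
    )
    df <- dplyr::rename(df, gene_id = "genes")
  } else {
    df <- pathways
  }
  read_pathway_table(as.data.frame(df))
}

#' Write a pathway database back to its flat TSV dialect
#'
#' Inverse of [read_pathway_table()]; a read/write round trip is
#' content-identical up to row order.
#'
#' @param db a `pathway_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(db, path) {
  long <- pathway_links(db)
  readr::write_tsv(long, path)
  invisible(path)
}

#' Long (one row per pathway--gene link) view of a database
#'
#' @param db a `pathway_db`.
#' @return tibble `pathway_id`, `pathway_name`, `class_path`, `gene_id`
#'   (empty string for gene-less pathways, mirroring the file dialect).
#' @export
pathway_links <- function(db) {
  db |>
    tibble::as_tibble() |>
    dplyr::mutate(gene_id = purrr::map(.data$genes, ~ if (length(.x) == 0) "" else .x)) |>
    dplyr::select("pathway_id", "pathway_name", "class_path", "gene_id") |>
    tidyr::unnest("gene_id")
}

#' Look up the pathways a locus belongs to
#'
#' A locus may belong to many pathways; an unknown locus simply belongs to
#' none.
#'
#' @param db a `pathway_db`.
#' @param locus_id single locus identifier (case-sensitive).
#' @return character vector of pathway ids (possibly empty), sorted.
#' @export
pathways_of_locus <- function(db, locus_id) {
  stopifnot(length(locus_id) == 1)
  hits <- purrr::map_lgl(db$genes, ~ locus_id %in% .x)
  sort(db$pathway_id[hits])
}

# locus -> pathways inverted index as a long tibble (internal work-horse for
# call_pathways; kept consistent with pathways_of_locus by construction).
locus_index <- function(db) {
  db |>
    tibble::as_tibble() |>
    dplyr::select("pathway_id", "genes") |>
    tidyr::unnest_longer("genes", values_to = "locus_id") |>
    dplyr::filter(!is.na(.data$locus_id))
}

#' Read a probe-to-locus translation table
#'
#' @param source path to a TSV with header `probe_id	locus_id`, or an
#'   equivalent data frame.
#' @return tibble with unique `probe_id` keys and non-empty `locus_id`
#'   values.
#' @export
read_probe_map <- function(source) {
  map <- read_tsv_checked(source, required = c("probe_id", "locus_id"),
                          what = "probe map")
  map <- dplyr::mutate(map, dplyr::across(dplyr::everything(),
                                          ~ trimws(as.character(.x))))
  if (anyDuplicated(map$probe_id)) {
    abort_consistency("probe map: duplicate probe_id keys")
  }
  if (any(is.na(map$locus_id) | map$locus_id == "")) {
    abort_format("probe map: locus_id values must be non-empty")
  }
  tibble::as_tibble(map)
}

#' Translate probe-keyed DE records to locus keys
#'
#' Each probe id is replaced by its locus id; probes absent from the map are
#' dropped (the translation is lossy by design) and their count is reported
#' via a warning and the `n_unmapped` attribute.  Multiple probes mapping to
#' one locus are preserved as separate evidence rows.
#'
#' @param records tibble of DE records with a `gene_id` column holding probe
#'   ids (see [read_de_table()]).
#' @param probe_map tibble from [read_probe_map()].
#' @return `records` with `gene_id` replaced by locus ids; attribute
#'   `n_unmapped` holds the number of dropped rows.
#' @export
translate_probes <- function(records, probe_map) {
  matched <- dplyr::inner_join(records, probe_map,
                               by = c(gene_id = "probe_id"))
  n_unmapped <- nrow(records) - nrow(matched)
  out <- matched |>
    dplyr::mutate(gene_id = .data$locus_id) |>
    dplyr::select(-"locus_id")
  if (n_unmapped > 0) {
    rlang::warn(sprintf("translate_probes: %d unmapped probe(s) dropped",
                        n_unmapped))
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# Shared TSV reader: accepts a path or a data frame, enforces the header.
read_tsv_checked <- function(source, required, what) {
  if (is.data.frame(source)) {
    df <- tibble::as_tibble(source)
  } else {
    df <- readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf("%s: missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  df
}
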