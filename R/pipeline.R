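#' Configure a full pipeline run
#'
#' @param pathway_db path to the pathway--gene association TSV.
#' @param probe_map path to the probe-to-locus TSV, or `NULL` when DE
#'   tables are already locus-keyed.
#' @param de_tables named character vector of the four DE table paths,
#'   names drawn from the contrast labels.
#' @param out_dir output directory.
#' @param fc_threshold,q_threshold significance thresholds (defaults 2.0
#'   and 0.05).
#' @param verbose print per-stage progress and the mapped-gene ratio per
#'   contrast (the pipeline's QC statistic: mapped DE genes / all DE
#'   genes).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pathway_db, probe_map = NULL, de_tables,
                            out_dir, fc_threshold = 2, q_threshold = 0.05,
                            verbose = TRUE) {
  assert_contrast(names(de_tables))
  if (!setequal(names(de_tables), contrast_labels())) {
    abort_format("pipeline_config: de_tables must name all four contrasts")
  }
  paths <- c(pathway_db, probe_map, unname(de_tables))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_format(sprintf("pipeline_config: input file(s) not found: %s",
                         paste(missing, collapse = ", ")))
  }
  structure(
    list(pathway_db = pathway_db, probe_map = probe_map,
         de_tables = de_tables[contrast_labels()], out_dir = out_dir,
         fc_threshold = fc_threshold, q_threshold = q_threshold,
         verbose = verbose),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; `de_tables` is a
#' mapping from contrast label to file path.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(
    pathway_db = cfg$pathway_db,
    probe_map = cfg$probe_map,
    de_tables = unlist(cfg$de_tables),
    out_dir = cfg$out_dir %||% ".",
    fc_threshold = cfg$fc_threshold %||% 2,
    q_threshold = cfg$q_threshold %||% 0.05,
    verbose = cfg$verbose %||% TRUE
  )
}

#' Run the full pathway-contrast pipeline
#'
#' Reads the pathway database and the four per-contrast DE tables,
#' translates probes to loci (if a probe map is given), applies the
#' significance filter, calls pathway-level regulation per contrast,
#' assembles regulation patterns, partitions them across the Venn
#' categories, applies the resistance and susceptibility class rules, and
#' tabulates calls by category.  All outputs are written as TSVs under
#' `out_dir` together with a run manifest (input hashes, thresholds,
#' package version); identical inputs give byte-identical outputs.
#'
#' @param config a `pipeline_config` (or path to a YAML/JSON config file).
#' @return invisibly, a list with `calls`, `patterns`, `venn`,
#'   `classification`, `category_table`, `mapped_ratio`, and the output
#'   file paths.  Errors are re-signalled with the failing stage name.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s': %s", name, conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  db <- stage("pathway_db", read_pathway_table(config$pathway_db))
  pmap <- if (!is.null(config$probe_map)) {
    stage("probe_map", read_probe_map(config$probe_map))
  }

  calls <- list()
  mapped_ratio <- stats::setNames(numeric(4), contrast_labels())
  for (ct in contrast_labels()) {
    de <- stage(paste0("de_input:", ct),
                read_de_table(config$de_tables[[ct]], contrast = ct))
    sig <- filter_significant(de, config$fc_threshold, config$q_threshold)
    if (!is.null(pmap)) {
      sig <- suppressWarnings(translate_probes(sig, pmap))
    }
    mapped <- sum(unique(sig$gene_id) %in% locus_index(db)$locus_id)
    n_sig <- dplyr::n_distinct(sig$gene_id)
    mapped_ratio[ct] <- if (n_sig > 0) mapped / n_sig else NA_real_
    say("%s: %d significant loci, mapped-gene ratio %.1f%%",
        ct, n_sig, 100 * mapped_ratio[ct])
    calls[[ct]] <- stage(paste0("pathway_calls:", ct),
                         call_pathways(sig, db, ct))
  }

  patterns <- stage("build_patterns", build_patterns(calls))
  venn <- if (nrow(patterns) > 0) {
    stage("venn_partition", venn_partition(patterns))
  } else {
    venn_partition(patterns[0, ])
  }
  classification <- stage("classify", classify_pathways(patterns))
  category_table <- stage("tabulate_by_category",
                          tabulate_by_category(patterns, db))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_outputs(config, db, calls, patterns, venn, classification,
                         category_table, mapped_ratio)
  say("outputs written to %s", config$out_dir)
  invisible(list(calls = dplyr::bind_rows(calls), patterns = patterns,
                 venn = venn, classification = classification,
                 category_table = category_table,
                 mapped_ratio = mapped_ratio, paths = paths))
}

write_outputs <- function(config, db, calls, patterns, venn, classification,
                          category_table, mapped_ratio) {
  out <- config$out_dir
  paths <- c(calls = file.path(out, "pathway_calls.tsv"),
             patterns = file.path(out, "patterns.tsv"),
             venn = file.path(out, "venn.tsv"),
             classes = file.path(out, "classes.tsv"),
             categories = file.path(out, "category_table.tsv"),
             manifest = file.path(out, "manifest.json"))

  flat_calls <- dplyr::bind_rows(calls) |>
    dplyr::mutate(genes = purrr::map_chr(.data$evidence,
                                         ~ paste(unique(.x$locus_id), collapse = ","))) |>
    dplyr::select("pathway_id", "contrast", "direction", "n_genes", "genes")
  readr::write_tsv(flat_calls, paths[["calls"]])

  readr::write_tsv(format_patterns(patterns), paths[["patterns"]])

  venn_flat <- dplyr::mutate(
    tibble::as_tibble(venn),
    pathway_ids = purrr::map_chr(.data$pathway_ids, paste, collapse = ",")
  )
  readr::write_tsv(venn_flat, paths[["venn"]])

  classes <- tibble::as_tibble(classification) |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(db), "pathway_id",
                                   "pathway_name"),
                     by = "pathway_id") |>
    dplyr::select("pathway_id", "pathway_name", "resistance_class",
                  "susceptibility_class", dplyr::all_of(contrast_labels()))
  classes[contrast_labels()] <-
    format_patterns(patterns)[match(classes$pathway_id, patterns$pathway_id),
                              contrast_labels()]
  readr::write_tsv(classes, paths[["classes"]])

  readr::write_tsv(category_table, paths[["categories"]])

  inputs <- c(pathway_db = config$pathway_db,
              if (!is.null(config$probe_map)) c(probe_map = config$probe_map),
              config$de_tables)
  manifest <- list(
    tool = "pathcontrast",
    version = as.character(utils::packageVersion("pathcontrast")),
    thresholds = list(fold_change = config$fc_threshold,
                      q_value = config$q_threshold),
    inputs = as.list(unname(tools::md5sum(unlist(inputs)))) |>
      rlang::set_names(names(inputs)),
    mapped_gene_ratio = as.list(mapped_ratio)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
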