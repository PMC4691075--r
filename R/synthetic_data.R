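#' Configure a synthetic four-contrast experiment
#'
#' Builds the configuration for [simulate_experiment()]: a pathway
#' database with known membership, a probe map, and four DE tables in
#' which chosen pathways carry *planted* regulation patterns while the
#' remaining genes are background.  Planted signals are generated so that
#' the standard significance filter (ratio >= 2, q < 0.05) recovers them
#' exactly; background genes pass the filter independently with
#' `background_de_prob` per contrast.
#'
#' @param n_pathways number of pathways in the database.
#' @param genes_per_pathway_mean mean of the (shifted Poisson, minimum 1)
#'   genes-per-pathway count distribution.
#' @param n_background_genes genes outside any pathway.
#' @param planted data frame with column `pathway` (1-based pathway index)
#'   and any of the four contrast columns holding `up`/`down`/`mixed`
#'   (NA/missing = not regulated there), or `NULL` for no plants.
#' @param background_de_prob per-gene, per-contrast probability that a
#'   background gene is differentially expressed.
#' @param log2fc_location,log2fc_spread normal location/spread of the
#'   |log2 fold change| of DE genes, floored at 1 so the fold-change filter
#'   is the binding constraint, never the generator.
#' @param duplicate_probe_prob probability that a background gene gets a
#'   second probe; `conflict_prob` is the probability that such a
#'   duplicate reports the opposite direction (exercises the mixed-call
#'   logic).  Planted pathways always keep clean probes so plants stay
#'   recoverable.
#' @param conflict_prob see `duplicate_probe_prob`.
#' @param seed integer random seed; a fixed seed makes
#'   [simulate_experiment()] output byte-identical.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_pathways = 30,
                              genes_per_pathway_mean = 5,
                              n_background_genes = 200,
                              planted = NULL,
                              background_de_prob = 0,
                              log2fc_location = 1.5,
                              log2fc_spread = 0.5,
                              duplicate_probe_prob = 0,
                              conflict_prob = 0,
                              seed = 1L) {
  stopifnot(n_pathways >= 1, genes_per_pathway_mean >= 1,
            n_background_genes >= 0,
            background_de_prob >= 0, background_de_prob <= 1,
            log2fc_location >= 1,
            duplicate_probe_prob >= 0, duplicate_probe_prob <= 1,
            conflict_prob >= 0, conflict_prob <= 1)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot("pathway" %in% names(planted))
    if (any(planted$pathway < 1 | planted$pathway > n_pathways)) {
      rlang::abort("simulation_config: planted pathway index out of range")
    }
    if (anyDuplicated(planted$pathway)) {
      rlang::abort("simulation_config: a pathway may be planted only once")
    }
    for (ct in contrast_labels()) {
      planted[[ct]] <- if (ct %in% names(planted)) {
        parse_direction(planted[[ct]])
      } else {
        NA_character_
      }
    }
    planted <- dplyr::select(planted, "pathway", dplyr::all_of(contrast_labels()))
  }
  structure(
    list(n_pathways = as.integer(n_pathways),
         genes_per_pathway_mean = genes_per_pathway_mean,
         n_background_genes = as.integer(n_background_genes),
         planted = planted,
         background_de_prob = background_de_prob,
         log2fc_location = log2fc_location,
         log2fc_spread = log2fc_spread,
         duplicate_probe_prob = duplicate_probe_prob,
         conflict_prob = conflict_prob,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# category vocabulary for synthetic class paths (2 levels)
sim_category_pool <- function() {
  list(
    "Biosynthesis" = c("Amino acids biosynthesis",
                       "Secondary metabolites biosynthesis",
                       "Carbohydrates biosynthesis",
                       "Hormones biosynthesis"),
    "Degradation/Utilization/Assimilation" = c("Amino acids degradation",
                                               "Carbohydrates degradation",
                                               "Detoxification"),
    "Generation of Precursor Metabolites and Energy" = c("Fermentation",
                                                         "Glycolysis",
                                                         "Respiration")
  )
}

#' Generate a synthetic input bundle with planted pathway patterns
#'
#' @param config a [simulation_config()].
#' @return a `sim_bundle` list: `pathways` (a `pathway_db`), `probe_map`,
#'   `de_tables` (named list of four DE tibbles keyed by probe), `truth`
#'   (tibble of every pathway's planted pattern plus the class labels the
#'   published rules imply, derived by an independent rule evaluation),
#'   and `config`.
#' @details With `background_de_prob = 0`, running the pipeline on the
#'   bundle recovers every planted pattern and class label exactly; with
#'   noise, background DE genes can call unplanted pathways (one
#'   significant gene suffices), which is precisely the sensitivity the
#'   one-gene calling rule implies.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  npw <- config$n_pathways
  n_genes_pw <- 1L + stats::rpois(npw, config$genes_per_pathway_mean - 1)
  pathway_id <- sprintf("PWY-%04d", seq_len(npw))

  pool <- sim_category_pool()
  top <- sample(names(pool), npw, replace = TRUE)
  sub <- purrr::map_chr(top, ~ sample(pool[[.x]], 1))
  class_path <- paste(top, sub, sep = "|")

  total_pw_genes <- sum(n_genes_pw)
  all_loci <- sprintf("LOC_Os%05d", seq_len(total_pw_genes + config$n_background_genes))
  pw_gene_idx <- split(seq_len(total_pw_genes),
                       rep(seq_len(npw), times = n_genes_pw))
  genes <- purrr::map(pw_gene_idx, ~ all_loci[.x])

  db <- pathway_db(tibble::tibble(
    pathway_id = pathway_id,
    pathway_name = sprintf("synthetic pathway %d", seq_len(npw)),
    class_path = class_path,
    genes = genes
  ))

  planted <- config$planted
  planted_idx <- if (is.null(planted)) integer() else planted$pathway
  # planted gene set is fully controlled; everything else is background
  background_loci <- c(all_loci[unlist(pw_gene_idx[setdiff(seq_len(npw), planted_idx)],
                                       use.names = FALSE)],
                       all_loci[seq_len(config$n_background_genes) + total_pw_genes])

  # probes: one per locus; background loci may get a duplicate probe
  probe_rows <- tibble::tibble(locus_id = all_loci,
                               probe_id = sprintf("Probe.%05d_at", seq_along(all_loci)))
  if (config$duplicate_probe_prob > 0 && length(background_loci) > 0) {
    dup <- background_loci[stats::runif(length(background_loci)) <
                             config$duplicate_probe_prob]
    if (length(dup) > 0) {
      probe_rows <- dplyr::bind_rows(
        probe_rows,
        tibble::tibble(locus_id = dup,
                       probe_id = sprintf("Probe.%05d_x_at",
                                          match(dup, all_loci)))
      )
    }
  }
  # a single-gene pathway planted "mixed" anywhere needs a second probe on
  # its one locus so both directions can be expressed
  if (length(planted_idx) > 0) {
    mixed_any <- purrr::map_lgl(seq_along(planted_idx), function(k) {
      any(unlist(planted[k, contrast_labels()]) == "mixed", na.rm = TRUE)
    })
    for (pw in planted_idx[mixed_any]) {
      idx <- pw_gene_idx[[pw]]
      if (length(idx) == 1 &&
          !all_loci[idx] %in% probe_rows$locus_id[duplicated(probe_rows$locus_id) |
                                                    duplicated(probe_rows$locus_id,
                                                               fromLast = TRUE)]) {
        probe_rows <- dplyr::bind_rows(
          probe_rows,
          tibble::tibble(locus_id = all_loci[idx],
                         probe_id = sprintf("Probe.%05d_x_at", idx))
        )
      }
    }
  }
  probe_map <- dplyr::select(dplyr::arrange(probe_rows, .data$probe_id),
                             "probe_id", "locus_id")

  de_tables <- purrr::map(rlang::set_names(contrast_labels()), function(ct) {
    sim_contrast_table(ct, probe_rows, all_loci, pw_gene_idx, planted,
                       planted_idx, background_loci, config)
  })

  truth <- sim_truth(pathway_id, planted, planted_idx)

  structure(list(pathways = db, probe_map = probe_map, de_tables = de_tables,
                 truth = truth, config = config),
            class = "sim_bundle")
}

# one DE table (keyed by probe) for one contrast
sim_contrast_table <- function(ct, probe_rows, all_loci, pw_gene_idx, planted,
                               planted_idx, background_loci, config) {
  n_loci <- length(all_loci)
  # per-locus intended state for this contrast: "up", "down", or NA (not DE)
  state <- rep(NA_character_, n_loci)

  for (k in seq_along(planted_idx)) {
    pw <- planted_idx[k]
    dir <- planted[[ct]][k]
    idx <- pw_gene_idx[[pw]]
    if (is.na(dir)) next
    if (dir == "mixed") {
      if (length(idx) >= 2) {
        n_up <- max(1L, length(idx) %/% 2L)
        state[idx] <- c(rep("up", n_up), rep("down", length(idx) - n_up))
      } else {
        # single-gene pathway: the conflicting duplicate probe below
        # supplies the opposing direction
        state[idx] <- "up"
      }
    } else {
      state[idx] <- dir
    }
  }

  bg_idx <- match(background_loci, all_loci)
  if (config$background_de_prob > 0 && length(bg_idx) > 0) {
    hit <- bg_idx[stats::runif(length(bg_idx)) < config$background_de_prob]
    state[hit] <- sample(c("up", "down"), length(hit), replace = TRUE)
  }

  # per-probe records; duplicate probes follow their locus, possibly flipped
  tab <- probe_rows
  tab$locus_idx <- match(tab$locus_id, all_loci)
  tab$state <- state[tab$locus_idx]
  is_dup <- grepl("_x_at$", tab$probe_id)
  flip <- is_dup & !is.na(tab$state) &
    stats::runif(nrow(tab)) < config$conflict_prob
  tab$state[flip] <- ifelse(tab$state[flip] == "up", "down", "up")

  # single-gene mixed plants: the duplicate probe of that locus goes down
  for (k in seq_along(planted_idx)) {
    pw <- planted_idx[k]
    if (is.na(planted[[ct]][k]) || planted[[ct]][k] != "mixed") next
    idx <- pw_gene_idx[[pw]]
    if (length(idx) >= 2) next
    dup_rows <- which(tab$locus_id == all_loci[idx] &
                        grepl("_x_at$", tab$probe_id))
    tab$state[dup_rows] <- "down"
  }

  n <- nrow(tab)
  is_de <- !is.na(tab$state)
  mag <- pmax(1, stats::rnorm(n, config$log2fc_location, config$log2fc_spread))
  log2fc <- ifelse(is_de, ifelse(tab$state == "up", mag, -mag),
                   stats::runif(n, -0.9, 0.9))
  q <- ifelse(is_de, stats::runif(n, 0, 0.05 - 1e-9),
              stats::runif(n, 0.05, 1))

  tibble::tibble(
    contrast = ct,
    gene_id = tab$probe_id,
    fold_change = 2^log2fc,
    q_value = q
  ) |>
    dplyr::arrange(.data$gene_id)
}

# Ground-truth class labels by direct evaluation of the published rules,
# written independently of the classifier in venn_classify.R: presence
# sets and one explicit condition per class.
sim_truth <- function(pathway_id, planted, planted_idx) {
  truth <- tibble::tibble(pathway_id = pathway_id)
  for (ct in contrast_labels()) truth[[ct]] <- NA_character_
  if (length(planted_idx) > 0) {
    for (ct in contrast_labels()) {
      truth[[ct]][planted_idx] <- planted[[ct]]
    }
  }
  lab <- function(S, R, B, A, own, other) {
    reg <- function(x) !is.na(x)
    pure_opposed <- reg(R) && reg(S) &&
      sort(c(R, S))[1] == "down" && sort(c(R, S))[2] == "up"
    if (pure_opposed && reg(A)) return("III")
    if (!reg(other) && reg(own) && reg(A) && !reg(B)) return("I")
    if (!reg(other) && reg(own) && reg(A) && reg(B)) return("II")
    "none"
  }
  truth$resistance_class <- purrr::pmap_chr(
    truth[contrast_labels()],
    function(S6_S0, R6_R0, R0_S0, R6_S6) {
      lab(S6_S0, R6_R0, R0_S0, R6_S6, own = R6_R0, other = S6_S0)
    }
  )
  truth$susceptibility_class <- purrr::pmap_chr(
    truth[contrast_labels()],
    function(S6_S0, R6_R0, R0_S0, R6_S6) {
      lab(S6_S0, R6_R0, R0_S0, R6_S6, own = S6_S0, other = R6_R0)
    }
  )
  truth
}

#' Write a simulated bundle to disk as the standard input files
#'
#' Emits `pathways.tsv`, `probe_map.tsv`, `de_<contrast>.tsv` (x4) and
#' `truth.tsv` into `dir`.
#'
#' @param sim a `sim_bundle` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pathways = file.path(dir, "pathways.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    rlang::set_names(file.path(dir, sprintf("de_%s.tsv", contrast_labels())),
                     paste0("de_", contrast_labels())),
    truth = file.path(dir, "truth.tsv")
  )
  write_pathway_table(sim$pathways, paths[["pathways"]])
  readr::write_tsv(sim$probe_map, paths[["probe_map"]])
  for (ct in contrast_labels()) {
    readr::write_tsv(dplyr::select(sim$de_tables[[ct]], -"contrast"),
                     paths[[paste0("de_", ct)]])
  }
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Compare recovered class assignments against simulation ground truth
#'
#' @param assignments a `pathway_classification` over the simulated
#'   pathway universe (pathways without a row are taken as unclassed).
#' @param truth the `truth` tibble of a `sim_bundle`.
#' @return tibble with one row per (side, class): `n_true`, `n_assigned`,
#'   `n_correct`, `precision`, `recall` (NA where undefined).  Noise-free
#'   bundles must score precision = recall = 1 for every planted class.
#' @export
recovery_report <- function(assignments, truth) {
  asg <- tibble::as_tibble(assignments)
  extra <- setdiff(asg$pathway_id, truth$pathway_id)
  if (length(extra) > 0) {
    rlang::abort(sprintf(
      "recovery_report: assignment pathway(s) not in truth universe: %s",
      paste(extra, collapse = ", ")
    ))
  }
  joined <- truth |>
    dplyr::left_join(dplyr::select(asg, "pathway_id",
                                   pred_res = "resistance_class",
                                   pred_sus = "susceptibility_class"),
                     by = "pathway_id") |>
    dplyr::mutate(pred_res = dplyr::coalesce(.data$pred_res, "none"),
                  pred_sus = dplyr::coalesce(.data$pred_sus, "none"))

  one <- function(side, true_col, pred_col) {
    purrr::map_dfr(c("I", "II", "III"), function(cl) {
      tp <- sum(joined[[true_col]] == cl & joined[[pred_col]] == cl)
      n_true <- sum(joined[[true_col]] == cl)
      n_pred <- sum(joined[[pred_col]] == cl)
      tibble::tibble(
        side = side, class = cl, n_true = n_true, n_assigned = n_pred,
        n_correct = tp,
        precision = if (n_pred > 0) tp / n_pred else NA_real_,
        recall = if (n_true > 0) tp / n_true else NA_real_
      )
    })
  }
  dplyr::bind_rows(
    one("resistance", "resistance_class", "pred_res"),
    one("susceptibility", "susceptibility_class", "pred_sus")
  )
}
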