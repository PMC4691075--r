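#' Partition called pathways into the 15 four-set Venn categories
#'
#' Each pathway is assigned to exactly one category: the subset of the four
#' contrasts in which it has a call.  With four contrasts there are
#' 2^4 - 1 = 15 non-empty categories; categories are labelled by the
#' member contrasts joined with `+` in canonical order (`S6_S0`, `R6_R0`,
#' `R0_S0`, `R6_S6`).  The category sets are pairwise disjoint and cover
#' every input pathway (asserted on every run).
#'
#' @param patterns a `regulation_patterns` tibble; a pattern with no call
#'   in any contrast is rejected.
#' @return a `venn_partition` tibble: `category`, `n`, `pathway_ids`
#'   (list column), one row per non-empty category plus zero-count rows
#'   for empty categories so all 15 are always present.
#' @export
venn_partition <- function(patterns) {
  pat <- tibble::as_tibble(patterns)
  present <- purrr::map(seq_len(nrow(pat)), function(i) {
    contrast_labels()[!is.na(unlist(pat[i, contrast_labels()]))]
  })
  empty <- lengths(present) == 0
  if (any(empty)) {
    rlang::abort(sprintf(
      "venn_partition: pattern(s) with no call in any contrast: %s",
      paste(pat$pathway_id[empty], collapse = ", ")
    ))
  }
  category <- purrr::map_chr(present, paste, collapse = "+")

  all_cats <- venn_categories()
  out <- tibble::tibble(pathway_id = pat$pathway_id, category = category) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     pathway_ids = list(sort(.data$pathway_id)),
                     .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(category = all_cats), out,
                          by = "category") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pathway_ids = purrr::map(.data$pathway_ids, ~ if (is.null(.x)) character() else .x)
    )

  # partition property: disjoint cover of the input
  stopifnot(sum(out$n) == nrow(pat),
            !anyDuplicated(unlist(out$pathway_ids)),
            setequal(unlist(out$pathway_ids), pat$pathway_id))
  structure(out, class = c("venn_partition", class(tibble::tibble())))
}

#' All 15 non-empty contrast subsets in canonical order
#'
#' @return character vector of category labels, singletons first.
#' @export
venn_categories <- function() {
  labs <- contrast_labels()
  combos <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(labs, k), 2, paste, collapse = "+")
  }))
  combos
}

# -- class rules --------------------------------------------------------------
# The resistance rules, with S and R swapped for susceptibility:
#   Class I   : regulated in own temporal contrast, not in the other
#               genotype's; genotype difference after attack (R6_S6) but
#               not before (R0_S0).
#   Class II  : as Class I but the genotype difference exists both before
#               (R0_S0) and after (R6_S6) attack.
#   Class III : regulated in BOTH temporal contrasts with strictly opposing
#               pure directions (up vs down; mixed never opposes); genotype
#               difference after attack required, before-attack call free.
# Mixed counts as "differentially regulated" for the presence/absence tests
# of Classes I/II.  Class III is, by construction, identical between the
# resistance and susceptibility classifiers.

classify_one <- function(own, other, before, after) {
  has <- function(x) !is.na(x)
  opposing <- has(own) && has(other) &&
    ((own == "up" && other == "down") || (own == "down" && other == "up"))
  if (opposing && has(after)) return("III")
  if (has(own) && !has(other) && has(after)) {
    return(if (has(before)) "II" else "I")
  }
  "none"
}

#' Classify patterns under the resistance rules
#'
#' @param patterns a `regulation_patterns` tibble.
#' @return character vector (`"I"`, `"II"`, `"III"`, `"none"`) aligned with
#'   the rows of `patterns`.
#' @examples
#' p <- as_regulation_patterns(tibble::tibble(
#'   pathway_id = "betanidin degradation", R6_R0 = "down", R6_S6 = "lower"
#' ))
#' classify_resistance(p)  # "I"
#' @export
classify_resistance <- function(patterns) {
  pat <- tibble::as_tibble(patterns)
  purrr::pmap_chr(
    pat[contrast_labels()],
    function(S6_S0, R6_R0, R0_S0, R6_S6) {
      classify_one(own = R6_R0, other = S6_S0, before = R0_S0, after = R6_S6)
    }
  )
}

#' Classify patterns under the susceptibility rules
#'
#' Mirror of [classify_resistance()] with the genotype roles swapped; the
#' Class III condition is shared between the two classifiers.
#'
#' @inheritParams classify_resistance
#' @return character vector as in [classify_resistance()].
#' @export
classify_susceptibility <- function(patterns) {
  pat <- tibble::as_tibble(patterns)
  purrr::pmap_chr(
    pat[contrast_labels()],
    function(S6_S0, R6_R0, R0_S0, R6_S6) {
      classify_one(own = S6_S0, other = R6_R0, before = R0_S0, after = R6_S6)
    }
  )
}

#' Classify every pattern under both rule sets
#'
#' Convenience wrapper producing a classed result object with broom-style
#' [generics::tidy()] / [generics::glance()] methods and an
#' [ggplot2::autoplot()] visualisation.
#'
#' @param patterns a `regulation_patterns` tibble.
#' @return a `pathway_classification` tibble: the pattern columns plus
#'   `resistance_class` and `susceptibility_class`.
#' @export
classify_pathways <- function(patterns) {
  out <- tibble::as_tibble(patterns)
  out$resistance_class <- classify_resistance(patterns)
  out$susceptibility_class <- classify_susceptibility(patterns)
  structure(out, class = c("pathway_classification", class(tibble::tibble())))
}

#' @exportS3Method generics::tidy
tidy.pathway_classification <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.pathway_classification <- function(x, ...) {
  count_classes <- function(v) {
    c(I = sum(v == "I"), II = sum(v == "II"), III = sum(v == "III"))
  }
  r <- count_classes(x$resistance_class)
  s <- count_classes(x$susceptibility_class)
  tibble::tibble(
    n_pathways = nrow(x),
    resistance_I = r[["I"]], resistance_II = r[["II"]],
    resistance_III = r[["III"]], resistance_total = sum(r),
    susceptibility_I = s[["I"]], susceptibility_II = s[["II"]],
    susceptibility_III = s[["III"]], susceptibility_total = sum(s)
  )
}

#' @export
print.pathway_classification <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(
    "<pathway_classification> %d pathways | resistance I/II/III: %d/%d/%d | susceptibility I/II/III: %d/%d/%d\n",
    g$n_pathways, g$resistance_I, g$resistance_II, g$resistance_III,
    g$susceptibility_I, g$susceptibility_II, g$susceptibility_III
  ))
  NextMethod()
}

#' Group classed pathways under their category hierarchy
#'
#' A tabular stand-in for the hand-drawn pathway network figure: classed
#' pathways are grouped under their class-path branches with the direction
#' of the relevant temporal contrast attached (R6_R0 for
#' resistance-classed, S6_S0 for susceptibility-only pathways).
#'
#' @param assignments a `pathway_classification` whose `pathway_id`s name
#'   pathways of `db` (classed pathways missing from `db` are an error).
#' @param db a `pathway_db`.
#' @return tibble `branch` (top-level class label), `class_path`,
#'   `pathway_id`, `pathway_name`, `resistance_class`,
#'   `susceptibility_class`, `direction`, sorted by branch.
#' @export
network_table <- function(assignments, db) {
  classed <- dplyr::filter(
    tibble::as_tibble(assignments),
    .data$resistance_class != "none" | .data$susceptibility_class != "none"
  )
  if (nrow(classed) == 0) {
    return(tibble::tibble(branch = character(), class_path = character(),
                          pathway_id = character(), pathway_name = character(),
                          resistance_class = character(),
                          susceptibility_class = character(),
                          direction = character()))
  }
  missing <- setdiff(classed$pathway_id, db$pathway_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("network_table: classed pathway(s) absent from database: %s",
                         paste(missing, collapse = ", ")))
  }
  classed |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(db), "pathway_id", "pathway_name",
                    "class_path"),
      by = "pathway_id"
    ) |>
    dplyr::mutate(
      branch = purrr::map_chr(.data$class_path,
                              ~ strsplit(.x, "|", fixed = TRUE)[[1]][1]),
      direction = dplyr::if_else(.data$resistance_class != "none",
                                 .data$R6_R0, .data$S6_S0)
    ) |>
    dplyr::arrange(.data$branch, .data$class_path, .data$pathway_id) |>
    dplyr::select("branch", "class_path", "pathway_id", "pathway_name",
                  "resistance_class", "susceptibility_class", "direction")
}
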