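#' The four experimental contrasts
#'
#' The design compares a resistant (R) and a susceptible (S) rice genotype
#' before (0 h) and after (6 h) planthopper infestation.  Four pairwise
#' comparisons are analysed: two *temporal* contrasts within a genotype
#' (`R6_R0`, `S6_S0`; 6 h vs 0 h) and two *genotype* contrasts at one
#' timepoint (`R0_S0`, `R6_S6`; resistant vs susceptible).  The first-named
#' condition of each label is the fold-change numerator, so for genotype
#' contrasts "up" means higher in the resistant line.
#'
#' @return `contrast_labels()` returns the four labels in canonical table
#'   order (`S6_S0`, `R6_R0`, `R0_S0`, `R6_S6`); `contrast_kind()` returns
#'   `"temporal"` or `"genotype"` for each label passed in.
#' @param label character vector of contrast labels.
#' @examples
#' contrast_labels()
#' contrast_kind("R6_S6")
#' @export
contrast_labels <- function() {
  c("S6_S0", "R6_R0", "R0_S0", "R6_S6")
}

#' @rdname contrast_labels
#' @export
contrast_kind <- function(label) {
  assert_contrast(label)
  ifelse(label %in% c("R6_R0", "S6_S0"), "temporal", "genotype")
}

assert_contrast <- function(label, arg = "contrast") {
  bad <- setdiff(unique(label), contrast_labels())
  if (length(bad) > 0) {
    abort_format(sprintf(
      "unknown %s label(s): %s (expected one of %s)",
      arg, paste(bad, collapse = ", "), paste(contrast_labels(), collapse = ", ")
    ))
  }
  invisible(label)
}

# Canonical pathway-call directions.  Genotype contrasts render these as
# "higher"/"lower"/"higher/lower" for display; internally one vocabulary.
direction_levels <- function() c("up", "down", "mixed")

#' Render canonical directions in per-contrast vocabulary
#'
#' Temporal contrasts are reported as up/down/"up/down"; genotype contrasts
#' as higher/lower/"higher/lower".
#'
#' @param direction character vector of `"up"`, `"down"`, `"mixed"` (NA
#'   allowed, passed through).
#' @param contrast character vector of contrast labels, recycled against
#'   `direction`.
#' @return character vector in display vocabulary.
#' @examples
#' render_direction(c("up", "mixed"), c("R6_R0", "R6_S6"))
#' @export
render_direction <- function(direction, contrast) {
  assert_contrast(contrast)
  kind <- contrast_kind(contrast)
  out <- dplyr::case_when(
    is.na(direction) ~ NA_character_,
    kind == "temporal" & direction == "up" ~ "up",
    kind == "temporal" & direction == "down" ~ "down",
    kind == "temporal" & direction == "mixed" ~ "up/down",
    kind == "genotype" & direction == "up" ~ "higher",
    kind == "genotype" & direction == "down" ~ "lower",
    kind == "genotype" & direction == "mixed" ~ "higher/lower"
  )
  if (any(!is.na(direction) & is.na(out))) {
    abort_format("direction must be one of up, down, mixed (or NA)")
  }
  out
}

#' Parse display-vocabulary directions back to canonical form
#'
#' Accepts both the temporal (up/down/"up/down") and genotype
#' (higher/lower/"higher/lower") vocabularies; empty strings and NA become
#' NA (no call).
#'
#' @param x character vector of displayed directions.
#' @return character vector of `"up"`, `"down"`, `"mixed"`, or NA.
#' @export
parse_direction <- function(x) {
  x <- trimws(as.character(x))
  out <- dplyr::case_when(
    is.na(x) | x == "" ~ NA_character_,
    x %in% c("up", "higher") ~ "up",
    x %in% c("down", "lower") ~ "down",
    x %in% c("up/down", "higher/lower", "mixed") ~ "mixed"
  )
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    abort_format(sprintf(
      "unrecognised direction value(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

# -- error conditions ---------------------------------------------------------
# Two condition classes so callers (and the CLI) can distinguish malformed
# input (exit 2) from internally inconsistent input (exit 3).

abort_format <- function(msg) {
  rlang::abort(msg, class = "pathcontrast_format_error")
}

abort_consistency <- function(msg) {
  rlang::abort(msg, class = "pathcontrast_consistency_error")
}
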