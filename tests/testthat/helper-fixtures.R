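# In-code fixtures shared across test files.

toy_db <- function() {
  pathway_db(tibble::tibble(
    pathway_id = c("P1", "P2", "P3"),
    pathway_name = c("alpha", "beta", "gamma"),
    class_path = c("Biosynthesis|Amino acids biosynthesis",
                   "Biosynthesis|Secondary metabolites biosynthesis",
                   "Degradation/Utilization/Assimilation|Amino acids degradation"),
    genes = list(c("L1", "L2"), c("L2", "L3"), character())
  ))
}

de_tbl <- function(gene_id, fold_change, q_value, contrast = "R6_R0") {
  read_de_table(
    data.frame(gene_id = gene_id, fold_change = fold_change, q_value = q_value),
    contrast = contrast
  )
}

# random regulation patterns over a fixed direction alphabet; ensures at
# least one call per pathway
random_patterns <- function(n, seed) {
  set.seed(seed)
  states <- c(NA, "up", "down", "mixed")
  repeat {
    m <- matrix(sample(states, n * 4, replace = TRUE), nrow = n)
    if (all(rowSums(!is.na(m)) >= 1)) break
  }
  df <- tibble::tibble(pathway_id = sprintf("pw%03d", seq_len(n)))
  for (j in seq_along(contrast_labels())) df[[contrast_labels()[j]]] <- m[, j]
  as_regulation_patterns(df)
}

# every (absent/up/down/mixed)^4 pattern, one row each: the enumeration
# grid used by the brute-force classifier oracles
all_direction_patterns <- function() {
  states <- c(NA, "up", "down", "mixed")
  grid <- expand.grid(S6_S0 = states, R6_R0 = states, R0_S0 = states,
                      R6_S6 = states, stringsAsFactors = FALSE)
  grid$pathway_id <- sprintf("g%03d", seq_len(nrow(grid)))
  tibble::as_tibble(grid)
}

# Brute-force classifier oracle: a literal, per-row transcription of the
# published class rules, independent of the package implementation.
oracle_class <- function(row, side) {
  reg <- function(x) !is.na(x)
  if (side == "resistance") {
    own <- row$R6_R0; other <- row$S6_S0
  } else {
    own <- row$S6_S0; other <- row$R6_R0
  }
  before <- row$R0_S0; after <- row$R6_S6
  opposing <- reg(row$R6_R0) && reg(row$S6_S0) &&
    ((row$R6_R0 == "up" && row$S6_S0 == "down") ||
       (row$R6_R0 == "down" && row$S6_S0 == "up"))
  if (opposing && reg(after)) return("III")
  if (reg(own) && !reg(other) && reg(after) && !reg(before)) return("I")
  if (reg(own) && !reg(other) && reg(after) && reg(before)) return("II")
  "none"
}

oracle_classes <- function(patterns, side) {
  vapply(seq_len(nrow(patterns)),
         function(i) oracle_class(as.list(patterns[i, ]), side),
         character(1))
}
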