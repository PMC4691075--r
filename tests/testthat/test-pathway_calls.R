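test_that("pathway direction is the all-up/all-down/otherwise-mixed rule", {
  db <- toy_db()
  up <- filter_significant(de_tbl(c("L1", "L2"), c(2.5, 3.1), 0.01))
  calls <- call_pathways(up, db, "R6_R0")
  expect_equal(calls$direction[calls$pathway_id == "P1"], "up")

  mixed <- filter_significant(de_tbl(c("L1", "L2"), c(2.5, 0.4), 0.01))
  calls2 <- call_pathways(mixed, db, "R6_R0")
  expect_equal(calls2$direction[calls2$pathway_id == "P1"], "mixed")
  # L2 alone maps into P2: pure down there
  expect_equal(calls2$direction[calls2$pathway_id == "P2"], "down")

  none <- filter_significant(de_tbl("L9", 5, 0.001))
  expect_equal(nrow(call_pathways(none, db, "R6_R0")), 0)
})

test_that("a locus with conflicting probe directions injects both", {
  db <- toy_db()
  # same locus L1 significant up and down (two probes after translation)
  recs <- filter_significant(de_tbl(c("L1", "L1"), c(2.5, 0.3), 0.01))
  calls <- call_pathways(recs, db, "R6_R0")
  expect_equal(calls$direction[calls$pathway_id == "P1"], "mixed")
  ev <- calls$evidence[[which(calls$pathway_id == "P1")]]
  expect_setequal(ev$direction[ev$locus_id == "L1"], c("up", "down"))
})

test_that("calls are independent of input record order", {
  db <- toy_db()
  recs <- filter_significant(de_tbl(c("L1", "L2", "L3"), c(2.5, 0.4, 8), 0.01))
  a <- call_pathways(recs, db, "R6_R0")
  b <- call_pathways(recs[c(3, 1, 2), ], db, "R6_R0")
  expect_equal(a, b)
})

test_that("adding genes moves calls monotonically toward mixed", {
  db <- toy_db()
  base <- filter_significant(de_tbl("L1", 2.5, 0.01))
  more_up <- filter_significant(de_tbl(c("L1", "L2"), c(2.5, 4), 0.01))
  with_down <- filter_significant(de_tbl(c("L1", "L2"), c(2.5, 0.4), 0.01))
  dir_of <- function(r) {
    cl <- call_pathways(r, db, "R6_R0")
    cl$direction[cl$pathway_id == "P1"]
  }
  expect_equal(dir_of(base), "up")
  expect_equal(dir_of(more_up), "up")
  expect_equal(dir_of(with_down), "mixed")
})

test_that("called-pathway count equals pathways with >=1 significant gene", {
  set.seed(11)
  for (rep in 1:5) {
    db <- pathway_db(tibble::tibble(
      pathway_id = sprintf("P%d", 1:6),
      pathway_name = sprintf("p%d", 1:6),
      class_path = "Biosynthesis",
      genes = lapply(1:6, function(i) sprintf("L%d", sample(1:12, 3)))
    ))
    recs <- filter_significant(
      de_tbl(sprintf("L%d", 1:12), 2^runif(12, -3, 3), runif(12, 0, 0.1)))
    calls <- call_pathways(recs, db, "R6_R0")
    brute <- sum(vapply(db$genes, function(g) any(g %in% recs$gene_id),
                        logical(1)))
    expect_equal(nrow(calls), brute)
  }
})

test_that("patterns assemble one row per pathway with absent contrasts NA", {
  calls <- tibble::tibble(
    pathway_id = c("P", "P"), contrast = c("R6_R0", "R6_S6"),
    direction = c("down", "down")
  )
  pat <- build_patterns(calls)
  expect_equal(nrow(pat), 1)
  expect_equal(pat$R6_R0, "down")
  expect_equal(pat$R6_S6, "down")
  expect_true(is.na(pat$S6_S0) && is.na(pat$R0_S0))
  expect_equal(format_patterns(pat)$R6_S6, "lower")

  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_error(build_patterns(dup), class = "pathcontrast_consistency_error")
})

test_that("category tabulation equals a brute-force group-by count", {
  pat <- random_patterns(20, seed = 3)
  db <- pathway_db(tibble::tibble(
    pathway_id = pat$pathway_id,
    pathway_name = pat$pathway_id,
    class_path = sample(c("Biosynthesis|Amino acids biosynthesis",
                          "Biosynthesis|Secondary metabolites biosynthesis",
                          "Degradation/Utilization/Assimilation|Detoxification"),
                        20, replace = TRUE),
    genes = replicate(20, "L1", simplify = FALSE)
  ))
  tab <- tabulate_by_category(pat, db, level = 2)
  for (ct in contrast_labels()) {
    for (k in seq_len(nrow(tab))) {
      cat_k <- tab$category[k]
      ids <- db$pathway_id[vapply(strsplit(db$class_path, "|", fixed = TRUE),
                                  function(p) p[min(2, length(p))] == cat_k,
                                  logical(1))]
      brute <- sum(!is.na(pat[[ct]][pat$pathway_id %in% ids]))
      expect_equal(tab[[ct]][k], brute)
    }
  }
  # a pathway called in two contrasts appears in both columns
  two <- as_regulation_patterns(tibble::tibble(
    pathway_id = "pw001", R6_R0 = "up", S6_S0 = "down"))
  tab2 <- tabulate_by_category(two, db, level = 1)
  expect_equal(tab2$R6_R0[1], 1L)
  expect_equal(tab2$S6_S0[1], 1L)

  expect_error(tabulate_by_category(
    as_regulation_patterns(tibble::tibble(pathway_id = "ghost", R6_R0 = "up")),
    db), "ghost")
})

test_that("shared/unique tallies match brute-force set algebra", {
  pat <- as_regulation_patterns(tibble::tibble(
    pathway_id = c("a", "b", "c", "d"),
    R6_R0 = c("up", "up", NA, "mixed"),
    S6_S0 = c("up", NA, "up", "up")
  ))
  out <- shared_unique_counts(pat)
  up <- out[out$direction == "up", ]
  expect_equal(up$shared, 1)         # only "a"; mixed "d" excluded
  expect_equal(up$unique_R6_R0, 1)   # "b"
  expect_equal(up$unique_S6_S0, 2)   # "c" and "d" (d is pure up in S)

  # randomised brute-force check
  rnd <- random_patterns(40, seed = 9)
  out2 <- shared_unique_counts(rnd)
  for (dir in c("up", "down")) {
    r <- rnd$pathway_id[!is.na(rnd$R6_R0) & rnd$R6_R0 == dir]
    s <- rnd$pathway_id[!is.na(rnd$S6_S0) & rnd$S6_S0 == dir]
    row <- out2[out2$direction == dir, ]
    expect_equal(row$shared, length(intersect(r, s)))
    expect_equal(row$unique_R6_R0, length(setdiff(r, s)))
    expect_equal(row$unique_S6_S0, length(setdiff(s, r)))
  }
})
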