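test_that("venn partition assigns each pathway to its contrast subset", {
  pat <- as_regulation_patterns(tibble::tibble(
    pathway_id = c("solo", "all4"),
    S6_S0 = c(NA, "up"), R6_R0 = c("down", "up"),
    R0_S0 = c(NA, "up"), R6_S6 = c(NA, "mixed")
  ))
  vp <- venn_partition(pat)
  expect_equal(nrow(vp), 15)
  expect_equal(vp$pathway_ids[[which(vp$category == "R6_R0")]], "solo")
  expect_equal(vp$pathway_ids[[which(vp$category == "S6_S0+R6_R0+R0_S0+R6_S6")]],
               "all4")
  expect_error(venn_partition(tibble::tibble(
    pathway_id = "x", S6_S0 = NA_character_, R6_R0 = NA_character_,
    R0_S0 = NA_character_, R6_S6 = NA_character_
  )), "no call")
})

test_that("venn partition is a disjoint cover on random pattern sets", {
  for (seed in 1:10) {
    pat <- random_patterns(100, seed = seed)
    vp <- venn_partition(pat)
    ids <- unlist(vp$pathway_ids)
    expect_equal(sort(ids), sort(pat$pathway_id))   # cover, no duplicates
    # brute-force subset assignment oracle
    for (i in seq_len(nrow(pat))) {
      subset_i <- contrast_labels()[!is.na(unlist(pat[i, contrast_labels()]))]
      cat_i <- paste(subset_i, collapse = "+")
      expect_true(pat$pathway_id[i] %in%
                    vp$pathway_ids[[which(vp$category == cat_i)]])
    }
  }
})

test_that("worked classification examples get the expected classes", {
  pat <- as_regulation_patterns(tibble::tibble(
    pathway_id = c("betanidin degradation", "Flavonoid biosynthesis",
                   "phenylalanine degradation III", "no R6_S6 call", "empty-ish"),
    S6_S0 = c(NA, NA, "up", "up", NA),
    R6_R0 = c("down", "down", "down", NA, "up"),
    R0_S0 = c(NA, "higher", NA, NA, NA),
    R6_S6 = c("lower", "higher", "lower", NA, NA)
  ))
  expect_equal(classify_resistance(pat), c("I", "II", "III", "none", "none"))
  expect_equal(classify_susceptibility(pat), c("none", "none", "III", "none", "none"))

  sus <- as_regulation_patterns(tibble::tibble(
    pathway_id = c("methylerythritol phosphate pathway", "ureide biosynthesis"),
    S6_S0 = c("down", "up"), R6_R0 = c(NA, "down"),
    R0_S0 = c("lower", "lower"), R6_S6 = c("lower", "lower")
  ))
  expect_equal(classify_susceptibility(sus), c("II", "III"))
})

test_that("classifier agrees with the brute-force oracle on all 256 patterns", {
  grid <- all_direction_patterns()
  pat <- as_regulation_patterns(grid)
  expect_equal(classify_resistance(pat), oracle_classes(grid, "resistance"))
  expect_equal(classify_susceptibility(pat), oracle_classes(grid, "susceptibility"))
})

test_that("each pattern gets at most one class per side; Class III is symmetric", {
  grid <- all_direction_patterns()
  pat <- as_regulation_patterns(grid)
  res <- classify_resistance(pat)
  sus <- classify_susceptibility(pat)
  expect_true(all(res %in% c("I", "II", "III", "none")))
  expect_true(all(sus %in% c("I", "II", "III", "none")))
  # Class III resistance <=> Class III susceptibility
  expect_equal(res == "III", sus == "III")
})

test_that("the published candidate patterns reproduce the reported grouping", {
  pat <- sbph_patterns(keep_reported = TRUE)
  cl <- classify_pathways(pat)
  expect_equal(cl$resistance_class, attr(pat, "reported_resistance_class"))
  expect_equal(cl$susceptibility_class, attr(pat, "reported_susceptibility_class"))
})

test_that("network table groups classed pathways under hierarchy branches", {
  pat <- sbph_patterns()
  db <- pathway_db(tibble::tibble(
    pathway_id = pat$pathway_id,
    pathway_name = pat$pathway_id,
    class_path = rep(c("Biosynthesis|Hormones biosynthesis",
                       "Degradation/Utilization/Assimilation|Amino acids degradation"),
                     length.out = nrow(pat)),
    genes = replicate(nrow(pat), "L1", simplify = FALSE)
  ))
  cl <- classify_pathways(pat)
  nt <- network_table(cl, db)
  expect_equal(nrow(nt), 25)
  # brute-force group-by: branch sizes add up
  expect_equal(sort(unname(table(nt$branch))),
               sort(unname(table(vapply(strsplit(db$class_path, "|", fixed = TRUE),
                                        `[[`, "", 1)))))
  # direction column carries the pathway's own temporal call
  expect_equal(nt$direction[nt$pathway_id == "Momilactone biosynthesis"], "up")
  expect_equal(nt$direction[nt$pathway_id == "thiamine biosynthesis"], "down")

  # one-level class path groups at root; missing pathway errors
  db1 <- pathway_db(tibble::tibble(pathway_id = "Betanidin degradation",
                                   pathway_name = "x", class_path = "Root",
                                   genes = list("L1")))
  cl1 <- classify_pathways(pat[pat$pathway_id == "Betanidin degradation", ])
  expect_equal(network_table(cl1, db1)$branch, "Root")
  expect_error(network_table(cl, db1), "absent from database")

  empty <- classify_pathways(random_patterns(3, 1)[0, ])
  expect_equal(nrow(network_table(empty, db)), 0)
})

test_that("glance counts classes and tidy returns the full table", {
  cl <- classify_pathways(sbph_patterns())
  g <- glance(cl)
  expect_equal(g$resistance_total,
               g$resistance_I + g$resistance_II + g$resistance_III)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("resistance_class", "susceptibility_class") %in% names(td)))
})
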