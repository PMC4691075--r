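# run the standard pipeline in memory on a simulated bundle
run_bundle <- function(sim) {
  calls <- lapply(contrast_labels(), function(ct) {
    sig <- filter_significant(sim$de_tables[[ct]])
    sig <- suppressWarnings(translate_probes(sig, sim$probe_map))
    call_pathways(sig, sim$pathways, ct)
  })
  classify_pathways(build_patterns(calls))
}

test_that("identical config and seed give byte-identical bundles", {
  cfg <- simulation_config(n_pathways = 8, n_background_genes = 40,
                           background_de_prob = 0.1,
                           duplicate_probe_prob = 0.3, conflict_prob = 0.5,
                           planted = data.frame(pathway = 2, R6_R0 = "up",
                                                R6_S6 = "up"),
                           seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim_bundle(simulate_experiment(cfg), d1)
  p2 <- write_sim_bundle(simulate_experiment(cfg), d2)
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # and a different seed changes the data
  cfg2 <- simulation_config(n_pathways = 8, n_background_genes = 40,
                            background_de_prob = 0.1, seed = 124)
  d3 <- withr::local_tempdir()
  p3 <- write_sim_bundle(simulate_experiment(cfg2), d3)
  expect_false(all(unname(tools::md5sum(p1)) == unname(tools::md5sum(p3))))
})

test_that("every generated significant gene obeys the thresholds and vice versa", {
  cfg <- simulation_config(n_pathways = 10, n_background_genes = 50,
                           background_de_prob = 0.2,
                           planted = data.frame(pathway = c(1, 2),
                                                R6_R0 = c("up", "mixed"),
                                                S6_S0 = c(NA, "down")),
                           seed = 5)
  sim <- simulate_experiment(cfg)
  for (ct in contrast_labels()) {
    de <- sim$de_tables[[ct]]
    sig <- filter_significant(de)
    passes <- (de$fold_change >= 2 | de$fold_change <= 0.5) & de$q_value < 0.05
    expect_equal(sort(sig$gene_id), sort(de$gene_id[passes]))
    # non-significant rows violate at least one bound
    non <- de[!de$gene_id %in% sig$gene_id, ]
    expect_true(all(non$fold_change > 0.5 & non$fold_change < 2 |
                      non$q_value >= 0.05))
  }
})

test_that("noise-free plants are recovered verbatim with their classes", {
  planted <- data.frame(
    pathway = 1:6,
    S6_S0 = c(NA, NA, "up", "down", NA, "mixed"),
    R6_R0 = c("down", "down", "down", NA, "up", "up"),
    R0_S0 = c(NA, "lower", NA, "lower", NA, "higher"),
    R6_S6 = c("lower", "lower", "lower", "lower", NA, "higher")
  )
  cfg <- simulation_config(n_pathways = 12, n_background_genes = 30,
                           background_de_prob = 0, planted = planted, seed = 42)
  sim <- simulate_experiment(cfg)
  cl <- run_bundle(sim)

  truth_called <- sim$truth[rowSums(!is.na(sim$truth[, contrast_labels()])) > 0, ]
  expect_equal(sort(cl$pathway_id), sort(truth_called$pathway_id))
  merged <- merge(as.data.frame(cl), truth_called, by = "pathway_id",
                  suffixes = c("", ".t"))
  for (ct in contrast_labels()) {
    expect_equal(merged[[ct]], merged[[paste0(ct, ".t")]])
  }
  rep <- recovery_report(cl, sim$truth)
  planted_classes <- rep[rep$n_true > 0, ]
  expect_true(all(planted_classes$precision == 1))
  expect_true(all(planted_classes$recall == 1))
})

test_that("random plants over several seeds match the independent rule oracle", {
  set.seed(99)
  for (seed in 1:5) {
    n <- 30
    states <- c(NA, "up", "down", "mixed")
    planted <- data.frame(pathway = 1:10)
    repeat {
      for (ct in contrast_labels()) {
        planted[[ct]] <- sample(states, 10, replace = TRUE)
      }
      if (all(rowSums(!is.na(planted[contrast_labels()])) >= 1)) break
    }
    cfg <- simulation_config(n_pathways = n, n_background_genes = 20,
                             background_de_prob = 0, planted = planted,
                             seed = seed)
    sim <- simulate_experiment(cfg)
    cl <- run_bundle(sim)
    # classifier output equals the ground-truth labels for every pathway
    truth <- sim$truth
    pred_res <- stats::setNames(rep("none", n), truth$pathway_id)
    pred_sus <- pred_res
    pred_res[cl$pathway_id] <- cl$resistance_class
    pred_sus[cl$pathway_id] <- cl$susceptibility_class
    expect_equal(unname(pred_res), truth$resistance_class)
    expect_equal(unname(pred_sus), truth$susceptibility_class)
    # and the truth labels agree with the test-local oracle
    expect_equal(truth$resistance_class,
                 oracle_classes(truth, "resistance"))
    expect_equal(truth$susceptibility_class,
                 oracle_classes(truth, "susceptibility"))
  }
})

test_that("recovery report counts confusion per class", {
  truth <- tibble::tibble(
    pathway_id = c("a", "b"),
    S6_S0 = c(NA, NA), R6_R0 = c("down", "up"),
    R0_S0 = c(NA, NA), R6_S6 = c("down", "up"),
    resistance_class = c("I", "I"), susceptibility_class = c("none", "none")
  )
  perfect <- classify_pathways(as_regulation_patterns(truth[, 1:5]))
  rep1 <- recovery_report(perfect, truth)
  res_I <- rep1[rep1$side == "resistance" & rep1$class == "I", ]
  expect_equal(res_I$precision, 1)
  expect_equal(res_I$recall, 1)

  # one planted pathway missed entirely -> recall drops
  partial <- perfect[perfect$pathway_id == "a", ]
  rep2 <- recovery_report(partial, truth)
  expect_equal(rep2$recall[rep2$side == "resistance" & rep2$class == "I"], 0.5)

  stranger <- classify_pathways(as_regulation_patterns(
    tibble::tibble(pathway_id = "zzz", R6_R0 = "up", R6_S6 = "up")))
  expect_error(recovery_report(stranger, truth), "not in truth universe")
})

test_that("unrealizable or invalid plants are rejected at config time", {
  expect_error(
    simulation_config(n_pathways = 3,
                      planted = data.frame(pathway = 5, R6_R0 = "up")),
    "out of range"
  )
  expect_error(
    simulation_config(n_pathways = 3,
                      planted = data.frame(pathway = c(1, 1), R6_R0 = "up")),
    "only once"
  )
})
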