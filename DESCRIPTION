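Package: pathcontrast
Title: Pathway-Level Contrast Analysis for Two-Genotype, Two-Timepoint
    Expression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling metabolic-pathway-level differential
    regulation from per-contrast differentially-expressed-gene tables, for
    partitioning called pathways across a four-contrast Venn diagram, and
    for rule-based nomination of resistance- and susceptibility-associated
    pathways in a resistant-versus-susceptible, before-versus-after
    infestation design.  Includes a synthetic-data generator that plants
    known pathway regulation patterns for end-to-end validation, and a
    free-amino-acid percent-change analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
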