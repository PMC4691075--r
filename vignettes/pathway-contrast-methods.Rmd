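---
title: "Pathway-level contrast analysis: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level contrast analysis: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcontrast)
```

## The experimental design and what the pipeline computes

pathcontrast analyses a 2 × 2 biotic-stress design: a resistant (R) and a
susceptible (S) plant genotype, each profiled before (0 h) and after (6 h)
insect infestation. Four pairwise expression comparisons result. The two
*temporal* contrasts, `R6_R0` and `S6_S0`, describe each genotype's own
response to attack; the two *genotype* contrasts, `R0_S0` and `R6_S6`,
describe the constitutive and the induced difference between the genotypes.
The first-named condition of each label is always the fold-change
numerator, so genotype contrasts are oriented resistant-over-susceptible
and their calls are rendered *higher*/*lower*.

The unit of interpretation is not the gene but the *metabolic pathway*,
looked up in a flat pathway–gene association table (the layout of a BioCyc
database dump: one row per pathway–gene link, category hierarchy
pipe-joined in one column). The pipeline moves through five steps, each an
exported function:

1. `read_de_table()` + `filter_significant()` — gene-level significance,
2. `translate_probes()` — array probe ids to genome locus ids,
3. `call_pathways()` + `build_patterns()` — pathway-level direction calls,
4. `venn_partition()` + `classify_pathways()` — set partition and the
   Class I–III rules,
5. `table_changes()` — the free-amino-acid percent-change analysis.

## Gene-level significance

A gene is differentially expressed in a contrast when its fold-change
ratio is at least 2.0 — or at most 0.5 for repression — **and** its
q-value is below 0.05. Both fold-change bounds are inclusive; the q bound
is strict. The down-bound at exactly 0.5 is kept as "down" for symmetry
with the inclusive up-bound. The thresholds are tunable
(`fc_threshold`, `q_threshold` in `pipeline_config()`), but 2.0 and 0.05
are the defaults because they are the convention of the upstream
microarray significance analysis whose output tables this package
consumes; the q-values themselves are inputs, never recomputed here.

Probe-to-locus translation is deliberately lossy: probes missing from the
translation table are dropped and counted, not raised as errors, because
array designs always contain probes with no genome locus. The mapped-gene
ratio (mapped DE genes / all DE genes) is logged per contrast as the
pipeline's QC statistic.

## The pathway call and its sensitivity

A pathway is *called* in a contrast as soon as one significant gene maps
to it; the call direction is **up** if every piece of evidence is up,
**down** if every piece is down, and **mixed** ("up/down", rendered
"higher/lower" for genotype contrasts) otherwise. Two consequences are
worth stating plainly:

* One gene suffices. Pathway calls are therefore sensitive to single
  false-positive genes, and the synthetic-data generator deliberately lets
  background DE genes land in unplanted pathways so that this sensitivity
  is visible in tests rather than hidden.
* A locus measured by several probes with conflicting directions
  contributes *both* directions, making the pathway mixed. Averaging the
  probes would discard the conflict; we preserve evidence instead.

`shared_unique_counts()` compares the two temporal responses: how many
purely up- (and purely down-) regulated pathways are shared between
`R6_R0` and `S6_S0`, and how many are unique to each. Mixed pathways are
excluded from these pure-direction tallies — a pathway that is "up/down"
is neither an up- nor a down-regulated pathway — but they do count in the
per-category tabulation (`tabulate_by_category()`), which counts *any*
differentially regulated pathway.

## The Venn partition and the Class I–III rules

`venn_partition()` assigns each called pathway to the subset of contrasts
in which it was called: 15 non-empty subsets for four contrasts. The
partition property (pairwise disjoint, covering) is asserted on every run,
not only in tests.

The classification rules nominate candidate pathways. Writing "regulated"
for any call (up, down or mixed):

| Class | own temporal | other temporal | `R0_S0` | `R6_S6` |
|-------|--------------|----------------|---------|---------|
| I     | regulated    | not            | not     | regulated |
| II    | regulated    | not            | regulated | regulated |
| III   | regulated, opposing pure directions in both | — | free | regulated |

"Own" is `R6_R0` for the resistance rules and `S6_S0` for the
susceptibility rules. Three design points were genuinely open and are
resolved as follows:

* **Class III's before-attack slot is unconstrained.** The published
  Class III examples disagree on whether `R0_S0` is filled, so the rule
  requires only the after-attack difference; the constitutive difference
  may or may not be present.
* **"Opposing" means strictly up vs down.** A mixed call contains both
  directions and would oppose everything and nothing; treating it as
  opposing would make the rule unfalsifiable. Only pure up against pure
  down qualifies, which also makes Class III provably symmetric between
  the two rule sets — a property the test suite checks over the complete
  4^4 = 256 pattern enumeration.
* **Mixed counts as "regulated" in the presence/absence slots.** "Up/down"
  is a regulation state, not an absence.

Susceptibility Class I is implemented even though the motivating dataset
had no member — the rule is well-defined, and the simulator can plant it.

## The free-amino-acid analysis

`percent_change(before, after)` is 100 × (after − before) / before,
rounded to one decimal *half away from zero* (the convention the published
concentration table follows: 895.65 → 895.7, −46.97 → −47.0; base R's
`round()` is banker's rounding and would disagree on ties).
`table_changes()` recomputes both genotypes' changes for every analyte,
recomputes the Total row twice (from the printed total concentrations and
as the sum of the analytes — the two need not agree, and both are
reported), and ranks the signed increases per genotype. Where a table
carries printed change columns, any row whose printed value differs from
the recomputation by more than 0.05 — more than rounding can explain — is
flagged in the `discrepant` column. In the packaged table five analytes
(methionine, cystine, aspartic acid, cystathionine, serine) are flagged in
both genotype columns; the package reports the conflict rather than
guessing which printed number is wrong.

## The synthetic-data generator

Real raw arrays for this design are not redistributable, so the package
generates its own validation data. `simulation_config()` +
`simulate_experiment()` build a pathway database (pathway sizes are
shifted-Poisson with minimum 1, category paths drawn from a small two-level
vocabulary), a probe map, and four DE tables in which chosen pathways carry
*planted* regulation patterns:

* A pathway planted "up" in a contrast has **all** member genes
  significant-up there; "down" symmetric; "mixed" gets at least one of
  each (a single-gene pathway planted mixed receives a second, conflicting
  probe on its one locus); "absent" means no member gene passes the filter.
* DE genes draw |log2 FC| from a normal (location 1.5, spread 0.5 by
  default) floored at 1, and q from U(0, 0.05); non-DE genes draw
  |log2 FC| < 0.9 and q from U(0.05, 1). The floor guarantees the
  significance filter, not the generator's tails, decides membership.
* Background genes (members of unplanted pathways, plus genes in no
  pathway) pass the filter independently with `background_de_prob` per
  contrast, with random direction. The default is 0 — the noise-free
  condition under which planted patterns must be recovered verbatim — and
  tests switch it on explicitly when they study false pathway calls.
* Everything is driven by one integer seed; the same configuration and
  seed produce byte-identical files.

The bundle's ground truth carries the planted pattern per pathway *and*
the class labels those patterns imply, derived by a rule evaluation
written independently of the pipeline's classifier, so truth and
implementation cannot share a bug silently. What the simulator does *not*
emulate: probe-intensity noise, normalisation artefacts, correlated genes
within a pathway, or pathway-size biases of real databases. Passing
recovery tests therefore demonstrate the *logic* of the pipeline, not its
robustness to upstream measurement error — the q-values and fold changes
are taken at face value by design.

## Numerical and degenerate-input choices

* Direction aggregation and all set operations are order-independent;
  pipeline outputs are byte-identical across reruns and carry a manifest
  of input MD5 hashes and thresholds.
* Pathways with no member genes parse and survive round trips but can
  never be called.
* An empty DE table produces an empty call list, an empty pattern table
  and an all-zero Venn partition, not an error; a pattern with no call in
  any contrast is rejected by `venn_partition()`.
* Duplicate (pathway, contrast) calls and conflicting pathway metadata are
  consistency errors (exit code 3 in the CLI wrapper); malformed files are
  format errors (exit code 2), reported with the offending data row.

## Problem sizes used in validation

The bundled checks run at desk scale, chosen so the full suite completes
in seconds while still exercising every rule path: the complete 256-pattern
enumeration for the classifiers, 1,000 random patterns for the partition
property, and noise-free recovery on bundles of 30 pathways (about 190
genes) across 5 seeds. The classification of the 25 published candidate
pathways and the amino-acid table are exact recomputations, not
simulations.

## Known limitations

* The pipeline consumes upstream fold changes and q-values; it cannot
  detect upstream normalisation problems.
* The one-gene calling rule is faithful to the method it implements but is
  aggressive; with noisy inputs, small pathways are easily called. The
  recovery report quantifies exactly this under simulation.
* The category tabulation assigns each pathway to a single hierarchy
  branch (its own class path); databases that file one pathway under
  multiple branches would need one row per filing.
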