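---
title: "Multi-cohort miRNA biomarker discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort miRNA biomarker discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircons)
```

## The problem

Individual miRNA expression studies of tumour versus normal tissue are
noisy and platform-dependent: a miRNA called differentially expressed in
one cohort frequently fails to replicate in the next. `mircons`
implements the integrative strategy used in colorectal-cancer biomarker
work: require a candidate miRNA to be differentially expressed in a
large reference cohort (a TCGA-style series) *and* in a minimum number
of independent supporting cohorts, with the same direction of regulation
everywhere it is significant. Candidates surviving this consensus are
then characterized three ways: through their experimentally validated
target genes (network crossing, expression correlation, pathway
over-representation), as diagnostic markers (ROC/AUC per cohort), and as
prognostic markers (median-split Kaplan–Meier/log-rank and Cox models,
including exhaustive screening of small miRNA panels).

Every stage consumes flat files (TSV expression matrices with a sidecar
label table, TSV clinical and interaction tables, GMT gene sets);
retrieval from GEO/Xena/miRBase/MirTarBase or any web service is out of
scope by design.

## Preprocessing

Two cleaning steps run per cohort, in a fixed order.

**Modified listwise deletion** (`filter_missing`). A miRNA is removed
when *more than* a threshold fraction (default 0.5) of its values are
missing in the tumour group **or** in the normal group, each fraction
taken over that group's own sample count. The inequality is strict: a
miRNA missing exactly half of each group is retained. This per-variable
rule is deliberately more conservative than classical listwise case
deletion, which would discard entire samples.

**Boxplot outlier masking** (`remove_outliers`). Within each miRNA and
class group, values strictly outside the Tukey fences
\[Q1 − k·IQR, Q3 + k·IQR\] (default k = 1.5) are set to missing.
Quartiles use linear interpolation between order statistics (`quantile`
type 7, the R default); fences are inclusive, so a degenerate group of
identical values loses nothing; the pass runs once (no iterated
re-fencing, which is not part of the boxplot rule). Groups with fewer
than 4 non-missing values are skipped with a warning because their
quartiles are unstable. Masking individual entries — rather than
dropping samples — is the only reading consistent with removing
"outlier values" per miRNA and group. The module operates on the log2
matrix; whether outlier removal should precede the log transform is a
genuinely open choice, and operating post-log matches the rest of the
pipeline's scale.

## Per-cohort differential testing

For each miRNA with at least 3 non-missing values per group,
`test_differential` runs Shapiro–Wilk on each group and declares the
pair *normal* only if both p-values exceed 0.05 (a per-group rule;
pooling the groups would conflate non-normality with the group shift
being tested).

Two test-selection policies are provided because published pipelines
state the branch both ways:

* `policy = "conventional"` (default): a normal pair goes to Levene's
  test (classic form, centered at the mean) for the equal-variance
  decision — Student's t when Levene p > 0.05, Welch's t otherwise; a
  non-normal pair goes to the two-sided Wilcoxon–Mann–Whitney test
  (exact for small tie-free samples, tie-corrected normal approximation
  otherwise).
* `policy = "paper_literal"`: the branches swap — normal pairs are sent
  to Mann–Whitney, non-normal pairs to Levene plus t-test. Some
  published descriptions read this way; the wording is almost certainly
  a transposition, but both readings are reproducible here, and every
  intermediate p-value plus the test actually used is recorded so runs
  are auditable.

Degenerate input (both groups constant and equal) returns p = 1 by
convention. P-values are Benjamini–Hochberg adjusted *within each
cohort* across all of its tested miRNAs — cohorts have different miRNA
inventories, so a pooled batch would mix incomparable families.
Significance means q ≤ 0.05.

Fold changes are reported in log2 with two modes: the default
difference of log2 group means, and the log2 ratio of linear-scale
group means. On log2 input these differ whenever within-group spread
differs; published methods are ambiguous about which scale the ratio is
taken on, so both are exposed rather than guessing (`fc_mode`).

## Consensus and direction consistency

`consensus_select` marks a miRNA selected when it is significant in the
designated reference cohort **and** in at least `min_support` (default
2) non-reference cohorts — with four cohorts, the reference plus two of
three supporters. `direction_filter` then keeps only selected miRNAs
whose fold-change sign agrees in *every* cohort where they are
significant; a single opposite cohort discards the candidate. Because
selection requires at least three significant cohorts, every surviving
miRNA has at least three concordant direction records. The result is
invariant to the order in which cohorts are supplied.

## Target network

* `filter_mti` keeps validated interactions for one species (default
  *Homo sapiens*) and, by default, only functionally supported evidence
  (support tags containing "weak" are excluded), deduplicating
  (miRNA, gene) pairs.
* `cross_disease_genes` restricts the network to a disease gene list
  (case-insensitive symbol match, no alias resolution) and ranks miRNAs
  by disease-target degree, keeping zero-degree miRNAs visible.
* `correlate_pair` mirrors the differential branch: Pearson when both
  vectors pass Shapiro–Wilk at 0.05, Spearman (tie-corrected)
  otherwise; strength is binned on the Mukaka scale (negligible < 0.30
  ≤ low < 0.50 ≤ moderate < 0.70 ≤ high < 0.90 ≤ very high, sign
  carried separately). Correlations run on tumour samples of the
  matched reference cohort by default (`tumour_only`); whether
  tumour-only or all matched samples is the right population is
  unstated in the source methodology, so it is a flag.
* `enrich_genesets` is a one-sided hypergeometric upper tail
  (`phyper`), with BH q-values across the collection. It replaces
  DAVID's web service; DAVID's EASE variant (overlap decremented by
  one) is available behind `ease = TRUE`. The default universe is all
  genes in the supplied collection, since no background is published.
* `mirna_pathway_matrix` reduces the network to a binary miRNA ×
  pathway incidence ("does some target of m lie in P"), the tabular
  equivalent of the usual pathway-crossing figure.

## Diagnostics

`compute_auc` computes the AUC as the Mann–Whitney U statistic over
n₁·n₀, ties counting ½ — identical to the probability that a random
tumour sample outranks a random normal one. Downregulated markers
separate classes with raw AUC near 0, so the reported `auc` is
orientation-resolved as max(A, 1 − A), with the orientation and the raw
value retained. The accuracy bins are: AUC = 1 perfect; 0.9 < AUC < 1
highly accurate; 0.7 < AUC ≤ 0.9 moderately accurate; 0.5 < AUC ≤ 0.7
less accurate; boundary values belong to the lower bin (0.9 is
"moderate"). No confidence interval is attached by default. When the
raw AUC is exactly 0.5 the orientation is reported as
`high_in_tumour`; the choice is arbitrary and affects nothing
downstream.

## Prognosis

`median_split` dichotomizes patients at the marker's median; "higher
expression" means strictly above, so ties go to the lower group. For
panels, `panel_groups` applies the **concordant-median** rule: higher =
above the median for *every* panel miRNA, lower = at-or-below for every
one, discordant patients excluded. The source methodology never defines
its multi-miRNA grouping, but its observation that larger panels shrink
the analyzable groups below 30 patients is only consistent with a rule
that discards discordant patients — a mean-of-z-scores median split
(`grouping = "meanscore"`), which preserves group sizes, is included
for sensitivity analysis. Medians are computed within the analyzed
(stage-specific, complete-case) patient set; patients missing any panel
value are excluded from that panel.

`screen_panels` enumerates every combination of `k_min`–`k_max`
candidate miRNAs (default 2–5; 25 candidates give 68,380 panels),
rejects panels whose smaller group falls below `min_group` (default
30) without testing them, and evaluates the rest with the log-rank test
(`survival::survdiff`) and a single-covariate Cox model
(`survival::coxph`, Efron ties). A panel "passes" at nominal log-rank
p < 0.05; no multiplicity correction is applied across panels by
default — matching how such screens are usually reported — but BH
q-values over the tested panels are emitted alongside. Complete
separation is flagged as non-converged rather than crashing. Stages
with fewer than 2·`min_group` eligible patients are skipped with a
report.

## The synthetic-data generator

`sim_config`/`simulate_study` generate the whole input universe with
planted ground truth, so every stage is testable offline:

* **Expression.** Per-miRNA baseline means from Uniform(4, 12) log2
  units, Gaussian noise (`noise_sd`, default 0.5 log2 units — tight
  enough that a −2 shift is clearly detectable at moderate n, typical
  of the separations such studies report). `n_true_de` miRNAs (default
  25) get a `de_shift` (default −2) added to tumour samples in every
  cohort carrying them.
* **Inventories.** A shared core of `mirna_overlap_fraction` (default
  0.8) of the inventory appears in all cohorts; the rest enters each
  cohort independently with probability ½. Planted miRNAs live in the
  core so the consensus rule can see them everywhere.
* **Contamination.** Missing entries completely at random
  (`missing_rate`, default 5%) and spike outliers of
  ±`outlier_magnitude` (default 6 log2 units, i.e. ≥ 6 noise SDs) at
  `outlier_rate` (default 1%) — the spike model is exactly what Tukey
  fences are meant to catch.
* **Survival.** Exponential event times with hazard
  `baseline_hazard`·exp(`panel_log_hr`·score), score = mean of the
  planted panel's standardized tumour expressions. Censoring is an
  independent exponential whose rate is solved numerically so the
  expected censored fraction equals `censor_rate` (a mean-hazard
  plug-in under-censors once the panel spreads the hazards);
  `censor_rate = 0` yields fully observed data. Stages are i.i.d. from
  `stage_probs`. Exponential hazards keep coverage checks closed-form;
  Weibull shapes are a non-goal.
* **Target layer.** Planted pairs couple gene to miRNA expression with
  population correlation `target_corr`, standardizing the miRNA
  profile *within each class* so the planted correlation holds both
  overall and inside the tumour-only subset used downstream; decoy
  genes are independent. The interaction table carries all true pairs,
  decoys, and a little weak-evidence/wrong-species chaff for the
  filter to remove.

All three generators are deterministic functions of `seed` (the
clinical and target layers use fixed small offsets of it).

What the generator does **not** emulate: platform- or batch-specific
noise, compositional sequencing effects, correlated miRNA co-regulation
beyond the planted structure, non-proportional hazards, and informative
censoring. Passing tests therefore demonstrate the pipeline's
statistical behaviour under a clean generative model, not robustness to
every artefact of real array/sequencing data.

## Verification strategy and problem sizes

The test suite checks each statistic against an independent brute-force
oracle (BH step-up by direct definition on 1,000 random vectors; exact
Mann–Whitney against exhaustive label permutation for n ≤ 10; AUC
against pairwise enumeration; log-rank against hand-built O/E/V tables;
hypergeometric tails against complete draw enumeration for N ≤ 12), a
set of hand-computed micro-examples, and Monte-Carlo calibration on the
generator: 200 null cohorts (40 miRNAs, 15+15 samples) for the FDR
rejection rate, 25 null and 25 planted four-cohort studies for
consensus specificity and sensitivity, and 50 replicates of a planted
3-miRNA panel (log HR = log 4, 300 stage-II patients) for screen power
— sizes chosen to make the Monte-Carlo error small relative to the
bounds being checked while keeping a full run in about a minute.

## Known limitations

* Gene symbols are matched case-insensitively with no alias resolution;
  identifier drift between the interaction table and the expression
  matrix silently reduces the evaluable edge set (it is reported, not
  resolved).
* The concordant-median rule is an inference from the group-shrinkage
  behaviour of the source methodology, not a documented reconstruction;
  the `meanscore` mode exists precisely to gauge its influence.
* The panel screen at nominal α reports many false positives by
  construction when thousands of panels are tested; the emitted BH
  column should be consulted before interpreting any single panel.
* A "Wilcox regression" step mentioned alongside Cox modelling in some
  descriptions of this workflow has no standard definition and is not
  implemented as a distinct procedure.
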