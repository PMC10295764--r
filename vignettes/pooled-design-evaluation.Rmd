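---
title: "Evaluating pooled-sample RNA-seq designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pooled-sample RNA-seq designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldeg)
```

## The question

A bulk RNA-seq comparison of two genotypes can sequence each biological
replicate individually, or mix equal RNA masses from the replicates into a
single pooled library. Pooling averages biological variation at the bench
instead of in the analysis: it is cheaper by a factor of the replicate
count, but the pooled sample carries no within-group variance, so
significance testing in the usual sense is impossible on the pooled side.
`pooldeg` provides a simulation-backed framework for asking what that
design choice costs in terms of the differentially expressed genes (DEGs)
actually recovered, plus the set-comparison statistics used to quantify
agreement between any two DEG lists.

## The generative model

`simulate_experiment()` draws a two-genotype experiment in three stages.

1. **Gene baselines.** Per-gene expected relative expression is log-normal:
   `exp(rnorm(n, baseline_log_mean, baseline_log_sd))`. The absolute scale
   is irrelevant because every sample is later rescaled to its library
   size; only the shape of the expression distribution matters. The default
   (meanlog 3, sdlog 1.5) spans roughly four orders of magnitude, a typical
   bulk dynamic range.
2. **Truth.** A fraction `frac_up` of genes is up-regulated and `frac_down`
   down-regulated in the mutant. True fold changes are log-uniform on
   `[fc_low, fc_high]`; down-regulated genes use the reciprocal of a draw
   from the same law, so effects are symmetric on the log scale. Everything
   else has fold change exactly 1.
3. **Counts.** Each sample's gene means are scaled to sum to its library
   size — the compositional renormalisation sequencing itself performs —
   and counts are drawn negative-binomially with variance
   \(m + \varphi m^2\) (`dispersion` = \(\varphi\); 0 gives the Poisson
   limit). The NB is the standard bulk RNA-seq noise model; nothing fancier
   (no dispersion–mean trend, no outlier genes) is layered on.

Defaults are fixed conventions chosen to resemble a worm-plate bulk
experiment: 12000 genes, six replicates per genotype, dispersion 0.05
(biological CV about 22% between genetically identical bulk samples,
i.e. smooth plate-level averages, not single-animal noise), library size
2×10⁶, and 10% of genes up-regulated at fold changes 2–8. They are
conventions, not estimates fitted to any particular deposited dataset.

One integer seed governs the whole package; sub-streams (gene parameters,
counts, pooling draws, study arms) are derived from it by fixed offsets, so
identical configurations are bit-identical and arms are independent yet
reproducible.

A consequence of the compositional renormalisation worth knowing: planting
many strongly up-regulated genes shrinks every observed ratio by the factor
\(\sum_g b_g / \sum_g b_g f_g\), exactly as real sequencing depth does. The
parameter-recovery tests therefore plant a small fraction of effect genes
when they assert that empirical mean ratios match the planted fold change.

## Equal-mass pooling

`pool_replicates()` models the pipette, not the sequencer: each selected
column is divided by its total (equal mass contributed per replicate,
regardless of how deeply that replicate would have been sequenced) and the
pooled profile is the unweighted mean of these proportion vectors. Two
modes separate the mixing arithmetic from sequencing noise:

* **expectation** — the profile times `pooled_library_size`, exact. The
  linearity invariant (pooled relative abundance = mean of replicate
  relative abundances) holds to the last bit and is asserted as such.
* **multinomial** — one multinomial draw of `pooled_library_size` reads
  from the profile, i.e. the pooled library as the sequencer samples it.
  As depth grows the drawn proportions converge to the expectation mode;
  the tests check this at two depths.

Expectation-mode pooled columns are fractional, so the count container
accepts nonnegative reals; simulated and multinomially pooled columns
remain integers.

## Expression unit and group summaries

All criteria operate on counts per million (`normalize_cpm()`): each column
scaled to sum to 10⁶. CPM is the minimal depth correction that makes
averages comparable across samples; gene length cancels because every
comparison is within a gene, and no between-sample distributional
normalisation (TMM, median-of-ratios, quantile) is applied — the criteria
are deliberately the simple arithmetic a spreadsheet could reproduce.

`group_summary()` computes, per gene, the wild-type mean, the mutant mean,
and the wild-type standard deviation with the *n* − 1 (sample) denominator
— one stated convention rather than a configurable choice, to keep results
reproducible. Pooled columns never enter `sd_wt` (a pooled library is not a
biological replicate); mutant pooled columns do enter `mean_mut`, so a
design with a single pooled mutant library summarises to that column
verbatim. A wild-type group consisting only of pooled columns is either an
error (`error_if_pooled_wt`) or summarised by mean alone with `sd_wt = NA`
(`exclude_pooled_from_sd`), in which case standard-deviation criteria
refuse to run.

## Criterion semantics and degenerate inputs

"Upregulated by T%" is read as mean ratio strictly above T/100 (500% → 5×),
not as ratio − 1 > T/100: the quantity compared to the threshold is the
plain ratio of averages. All thresholds are strict ("above"), so a gene at
exactly 3 standard deviations is not called at *k* = 3. Degenerate cases
have explicit conventions:

* `mean_wt = 0`, `mean_mut > 0`: ratio treated as +∞, called at any
  threshold; a gene silent in both groups is never called;
* `sd_wt = 0` with `mean_mut > mean_wt`: infinitely many standard
  deviations, called; `sd_wt = 0` without an increase: not called.

The combined criteria are literal conjunctions; their called set is
asserted (and tested on randomized summaries) to equal the intersection of
the constituent calls. The `down` direction mirrors every rule by swapping
the roles of the two means.

The significance route (`call_by_fdr()`) is a per-gene Welch *t* on
log₂(CPM + 1) with Benjamini–Hochberg adjustment (via `stats::p.adjust`),
rejection at adjusted p ≤ α, and a sign constraint for direction. It is the
simplest transparent test that respects unequal group variances; it is
*not* a reimplementation of any published DE tool, has no dispersion
shrinkage, and is accordingly conservative at three replicates per group
(Welch degrees of freedom near 4). The row-wise Welch statistic is computed
vectorised and cross-checked in the tests against `stats::t.test` gene by
gene; zero-variance rows get p = 1 when the means agree and p = 0
otherwise, so constant data yields no calls.

## Concordance statistics

For DEG sets A and B:

* **percent overlap** = 100·|A∩B| / min(|A|, |B|) — the smallest-set
  denominator, so nesting scores 100;
* **fold enrichment** = |A∩B| / (|A|·|B| / N) on an explicit background of
  N genes. The background is a required argument: no default universe is
  guessed, because the value is meaningless without one. Significance is
  the hypergeometric upper tail (`stats::phyper`), reported both on the
  natural scale and as log₁₀, since strong overlaps underflow double
  precision ("p = 0") while the log-scale tail remains informative;
* **identification** = 100·|C∩R|/|R| (recall) and **accuracy** =
  100·|C∩R|/|C| (precision) of a candidate C against a reference R;
* **multiway partitions** of up to four sets by exact membership pattern,
  with margins that reconstruct every input set.

Percentages are computed at full precision and additionally rounded half
away from zero for display (`round_half_up()`), because integer-percent
reporting is the field's habit; machine outputs always retain full
precision. Identifier harmonisation is an offline two-column mapping:
unmapped identifiers are dropped and reported rather than silently kept,
mirroring curation churn in which identifiers once reported as genes are
retired.

## The study driver

`run_simulation_study()` draws one biology (baselines, truth) from the
master seed, then independent counts per arm. Within each arm the mutant
side may be pooled; DEGs are called under every requested criterion; and
two reference sets anchor recovery statistics: the planted truth (available
only in simulation) and the intersection of the individually sequenced
arms' FDR-significant genes (the benchmark a real study would construct).
Both are reported because they answer different questions — recovery of
actual effects versus agreement with the replicate-based analysis.
The FDR criterion is marked inapplicable, not silently computed, for arms
whose mutant side is a single pooled library. Every percentage in the
report sits beside the counts it derives from, and the tests recompute each
one.

## What the tests show — and what they cannot

The test and acceptance suites run at sizes chosen to exercise the
statistics well while keeping a full run fast on one CPU: simulations of
600–12000 genes, Monte-Carlo moment checks at 500–1000 replicate columns,
20 null simulations of 2000 genes for the false-positive control, and
exhaustive hypergeometric enumeration over every background up to 25.

Passing them shows the arithmetic and the generative model are faithfully
implemented, that the significance route controls false positives under
the model's null, and that under generous planted effects pooling loses
little identification power. It does **not** show how pooling performs on
real data: the generator has no batch or collection-day effects, no
dispersion–mean trend, no gene-length artefacts, and no read-level
uncertainty (counts are the atomic unit). Conclusions about a particular
real experiment require that experiment's noise structure.

## Known limitations

* The FDR route is underpowered at very small replicate numbers compared
  with shrinkage-based DE tools; it is a transparent stand-in, not a
  replacement for them.
* Fold enrichment depends entirely on the supplied background size;
  comparisons across papers with unstated universes are not meaningful and
  are not attempted.
* Venn partitions are exact counts; no area-proportional drawing is
  provided.
```{r session}
sessionInfo()
```
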