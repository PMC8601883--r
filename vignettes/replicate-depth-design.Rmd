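---
title: "How many PCR replicates, how many reads: the models behind replidepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many PCR replicates, how many reads: the models behind replidepth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replidepth)
```

## The problem

An eDNA metabarcoding experiment turns a DNA extract into a
taxon-by-replicate table of read counts. Three experimental choices shape
every diversity number computed from that table:

* the **number of PCR replicates** amplified from the extract,
* the **read sampling depth** each replicate is rarefied to, and
* the **minimum read threshold** below which a count is treated as
  undetected.

Dominant taxa amplify consistently, but rare taxa are recovered
stochastically: a taxon at frequency 10^-4 is present or absent in a
5,000-read replicate essentially at random, and PCR noise adds further
between-replicate variation. replidepth implements the full analysis grid
that quantifies these effects — decontamination, rarefaction with
thresholds, alpha diversity with extrapolation, replicate accumulation,
occupancy, LCBD, ordination, and dispersion — together with a synthetic
experiment generator with known ground truth, so every stage is testable
without sequencing data.

## The synthetic experiment

`synthetic_config()` / `simulate_experiment()` emulate a soil eDNA
replication study: 6 extracts x 24 PCR replicates x 2 markers, plus four
extraction negatives, two PCR negatives, and one positive-control
replicate containing an exotic spike taxon.

The community and noise model is deliberately simple and fully
parameterized:

* **Rank abundances.** Each extract draws `richness_per_extract` taxa from
  a shared pool (so extracts overlap, as field sites do) and assigns them
  relative abundances either geometrically (`p_i` proportional to
  `g^(i-1)`) or lognormally (`p_i` proportional to `exp(z_i)`,
  `z_i ~ N(0, sigma^2)`). The defaults use the lognormal with `sigma = 3`:
  a handful of taxa at percent-to-tens-of-percent frequency on top of a
  long tail of taxa below 10^-4.
* **PCR stochasticity.** Replicate-level proportions are
  `Dirichlet(theta * p)`, counts are multinomial at a depth drawn from a
  truncated lognormal. The Dirichlet-multinomial keeps the marginal
  expectation at `p` for every `theta` while the between-replicate
  variance grows as `theta` shrinks; it reproduces the phenomenology that
  matters here (stochastic detection of rare taxa, the occupancy-abundance
  correlation) with two interpretable parameters, which is why we use it
  instead of a cycle-by-cycle PCR branching model.
* **Depths.** Per-replicate depths are drawn (not fixed) from a lognormal
  truncated to 6,148–166,279 reads, the retained-read range of the
  emulated study, so rarefaction drop-out occurs naturally.
* **Contaminants and index hopping.** A configurable number of contaminant
  taxa appear in negative controls at high prevalence and leak into true
  samples at low prevalence; a `hop_rate` fraction of positive-control
  spike reads is reassigned uniformly to other columns.
* **Seeding.** A single integer master seed feeds `derive_seed()`, which
  hashes the seed with the labels of each cell (replicate, depth,
  threshold, repeat). Any cell of any stage can be regenerated in
  isolation, and adding a stage never perturbs another stage's stream.

### Calibration of the defaults

The defaults (`richness_per_extract = 200`, lognormal `sigma = 3`,
`theta = 2000`) were fixed once by matching four summary statistics the
emulated study reports: per-replicate observed richness of a few dozen
taxa at a 5,000-read depth and threshold 5; a 21–29% share of taxa
detected in exactly one of 24 replicates; ubiquitous taxa at
percent-level within-replicate frequencies; and accumulation curves whose
saturation point rises with sampling depth and falls with the minimum
read threshold. The last pattern is diagnostic: communities much poorer
than ~200 taxa are essentially fully detected at 10,000 reads, which
*reverses* the depth trend, while much richer communities never saturate
within 24 replicates. `theta = 2000` encodes high-fidelity PCR —
replicates agree closely on common taxa (coefficient of variation around
20% for a 1% taxon), and occupancy becomes bimodal (taxa either
ubiquitous or seen once), as observed in real replicate panels.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, tag jumping at the sequence level), primer and amplification
bias that differs by taxon, taxonomy misassignment, and between-extract
heterogeneity in community structure beyond resampling a shared pool.
Passing tests therefore demonstrate that the *analysis machinery* behaves
correctly on data with the study's replicate/depth structure, not that
real soil communities follow a lognormal-Dirichlet-multinomial law.

## Decontamination and the index-hop check

`prevalence_scores()` compares presence/absence of each taxon between
true samples and pooled negative controls (extraction and PCR negatives
are one class; the emulated study does not distinguish them in the test).
The score is a one-sided p-value for enrichment in controls from the 2x2
table: chi-square with continuity correction when all expected cells are
at least 5, Fisher's exact test otherwise; taxa absent from all controls
score 1. A taxon is flagged when its score is below the prevalence
threshold (0.1 by default) and `remove_contaminants()` drops the whole
row — a contaminant is removed everywhere, not only in controls. The test
is applied to raw (unrarefied) counts; presence/absence is depth
sensitive, and we note but do not resolve that controls are usually much
shallower than samples.

`index_hop_check()` counts spike-taxon reads outside the positive-control
column and foreign reads inside it; a clean run reports rate 0.

## Rarefaction and minimum read thresholds

`rarefy()` subsamples **without replacement** (multivariate
hypergeometric). True subsampling of the sequenced pool has the clean
closed-form expectation

> E[S_d] = sum_i (1 - choose(N - x_i, d) / choose(N, d)),

which anchors the Monte-Carlo tests. Thresholding is **inclusive**
(`t = 5` keeps a taxon with exactly 5 reads, so `t = 2` removes exactly
the within-replicate singletons) and is applied **after** rarefaction,
per replicate. `rarefaction_grid()` averages `R = 25` draws per
(replicate, depth, threshold) cell by default and flags replicates whose
library is shallower than the target depth as dropped out rather than
erroring — the number retained per depth is reported alongside.

## Alpha diversity, extrapolation, outliers

Shannon uses natural logs and Simpson is the Gini–Simpson complement
`1 - sum(p^2)` (the defaults of the standard ecology implementations;
the source conventions vary, so ours are stated here). Richness curves
follow the sample-size-based Hill-number q = 0 formulas: interpolation by
the hypergeometric expectation above, extrapolation by

> S(n + m\*) = S_obs + f0 (1 - (1 - f1 / (n f0 + f1))^m\*),

with the Chao1-type `f0 = ((n-1)/n) f1^2 / (2 f2)` (the `f2 = 0` variant
when needed), so the asymptote is `S_hat = S_obs + f0` and the curve is
continuous at the reference depth. Curves run to twice the observed depth
on 40 knots; uncertainty comes from 50 bootstrap communities built from
coverage-shrunk observed proportions plus `ceiling(f0)` unseen taxa
sharing the coverage deficit, with normal-approximation confidence bands.

Outliers among per-replicate extrapolated richness values use the 1.5 x
IQR fence with type-7 (linear interpolation) quantiles — outlier flags
can flip under other quantile rules, so the rule is fixed and documented.
Replicates are extrapolated first and the outlier test is applied to the
resulting per-extract values. Depth contrasts use two-sided Welch t-tests
(the safer default when only "t-test" is specified) per extract and
index, plus the fold change of mean observed richness.

## Replicate accumulation and occupancy

`accumulation_curve()` shuffles the order in which replicates are pooled
(uniform permutations, not resampling; 100 shuffles by default) and
averages the cumulative unique-taxon count. The **saturation point** is
the smallest k whose next-step increment of the bootstrap-mean curve is
below one taxon; when no k within the retained replicates qualifies the
sentinel `">K"` is reported. Averaging happens over bootstraps *before*
the < 1 rule is applied.

`occupancy_records()` / `occupancy_abundance_fit()` regress occupancy
(replicates in which a taxon is detected) on log10 mean reads where
present. For a simple regression the slope's t, its p, and R^2 are the
same whichever variable is the response and whatever the log base, so
the direction/base choice affects only the slope's scale.

## Beta diversity

Binary Jaccard and Bray–Curtis dissimilarities feed three analyses:

* **LCBD.** Replicate-by-taxon data (Hellinger-transformed by default;
  `none` available since the upstream convention is not pinned down) are
  centered per taxon; each replicate's LCBD is its share of the total sum
  of squares, so LCBDs are non-negative and sum to one. Significance is
  by permuting values independently within each taxon (999 permutations
  by default), with Holm adjustment; a replicate is an LCBD outlier at
  adjusted p <= 0.05. All three choices (transform, permutation count,
  adjustment) are configurable and recorded in the output.
* **PCoA.** Gower double-centering and eigendecomposition. Jaccard is
  non-Euclidean, so negative eigenvalues occur; their axes are kept
  separately as "imaginary" coordinates for dispersion arithmetic while
  ordination output exposes positive axes only.
* **Dispersion.** Each group's spatial median (geometric median,
  iteratively reweighted with tolerance 1e-8) is located separately in
  the real and imaginary subspaces; squared imaginary distances are
  subtracted from squared real distances (floored at zero) — the
  PERMDISP2 convention. `bias_adjust = TRUE` multiplies each group's
  distances by `sqrt(n_g / (n_g - 1))`. Group differences are tested by
  one-way ANOVA on the distances, by label permutation with full
  recomputation of medians, and pairwise by Tukey HSD. Degenerate inputs
  (zero within- and between-group variance) report F = 0, p = 1.

Counts of LCBD outliers across depths, thresholds, or extracts are
compared by Pearson chi-square (Yates correction for 2x2 tables only).

## Numerical choices and degenerate inputs

* Interpolation evaluates `choose` ratios in log space; no overflow up to
  the deepest libraries the generator produces.
* Two empty columns have Jaccard distance 0 by convention; an all-equal
  table makes LCBD degenerate and the uniform `1/n` vector is returned
  with a flag rather than NaNs.
* Eigenvalues within `1e-9 * max|eigenvalue|` of zero are treated as
  null axes.
* Weiszfeld iterations cap point weights at `1/tol` when the iterate
  coincides with a data point.
* The saturation sentinel and rarefaction drop-outs are data, not errors:
  pipelines over grids must keep running when a cell is undefined.

## Problem sizes used in the checks

The packaged tests run the estimator oracles on tables up to 6 x 6
(tolerance 1e-9), the Monte-Carlo oracles at 10,000 rarefaction draws,
dispersion calibration on 500 null simulations, parameter recovery on 50
seeds, and the qualitative replicate/depth patterns on synthetic
experiments of 8–24 replicates over 10–20 seeds. `scripts/acceptance.R`
runs the full paper-shaped design (6 extracts x 24 replicates x 2
markers, depths 1k–20k, thresholds 2/5/10, 25 rarefactions per cell, 100
accumulation bootstraps) in a few minutes on one core. These sizes are
the package's own choices: large enough that every Monte-Carlo band in
the tests is computed from the simulation itself, small enough to run
routinely.

## Known limitations

* The contaminant score is a generic one-sided 2x2 association test at
  the published prevalence threshold, not a byte-level reimplementation
  of any particular decontamination package.
* Coverage-based (Chao–Jost) rarefaction, Hill numbers with q > 0,
  NMDS, PERMANOVA, and model-based ordination are out of scope.
* LCBD permutation p-values are discrete; with few replicates the
  smallest achievable p may exceed 0.05 and no outlier can be called.
* The synthetic generator's independence assumptions (taxa independent
  within the Dirichlet draw, extracts sharing a pool) understate real
  community structure; see the calibration section for what it does and
  does not match.
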