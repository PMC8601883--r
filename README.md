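# replidepth

How many PCR replicates does an eDNA metabarcoding experiment need, and
how deeply should each be sequenced? `replidepth` is an R package for
answering that question from taxon-by-replicate read-count tables. It
implements the full analysis grid over **read sampling depth** (rarefaction)
and **minimum read threshold**, applied per PCR replicate, and measures how
those choices move alpha- and beta-diversity estimates — together with a
synthetic experiment generator (6 DNA extracts x 24 PCR replicates x 2
markers by default, with negative and positive controls) so the entire
pipeline runs with known ground truth and no sequencing data.

## What it computes

* **Decontamination** — per-taxon prevalence comparison between true
  samples and pooled negative controls (one-sided 2x2 test, chi-square or
  Fisher as appropriate; flag at score < 0.1), plus a positive-control
  index-hop check on an exotic spike taxon.
* **Depth filters** — without-replacement rarefaction (multivariate
  hypergeometric), inclusive minimum read thresholds (`t = 2` removes
  exactly the singletons), and the mean richness over 25 draws for every
  (replicate, depth, threshold) cell, with drop-out bookkeeping.
* **Alpha diversity** — observed richness, Shannon (nats), Gini–Simpson;
  interpolated/extrapolated richness curves (Hill q = 0) to twice the
  observed depth with the Chao1-type asymptote
  `S_hat = S_obs + ((n-1)/n) f1^2 / (2 f2)` and bootstrap confidence
  bands; 1.5 x IQR outlier calls; Welch t-tests and fold changes between
  depths.
* **Replicate accumulation** — bootstrapped accumulation curves over
  shuffled replicate orders and the saturation point: the smallest number
  of replicates after which one more adds fewer than one taxon on
  average; occupancy spectra and the occupancy–abundance regression.
* **Beta diversity** — binary Jaccard and Bray–Curtis distances, local
  contributions to beta diversity (LCBD, a sum-to-one variance
  decomposition with permutation outlier tests), principal-coordinates
  ordination with proper handling of negative eigenvalues, and
  PERMDISP-style dispersion around group spatial medians with bias
  adjustment, ANOVA/permutation tests, and Tukey HSD.

See `vignette("replicate-depth-design")` for the models, parameter
meanings, and design decisions.

## A worked example

```r
library(replidepth)

cfg <- synthetic_config(n_extracts = 2, replicates_per_extract = 12,
                        markers = "PITS", seed = 42)
sim <- simulate_experiment(cfg)$PITS
sim$table
#> taxon_table: 282 taxa x 31 replicates
#> library depths: min 93, median 27858, max 157444

calls <- prevalence_scores(sim$table, sim$metadata)
subset(calls, is_contaminant)
#>           taxon_id prevalence_in_samples prevalence_in_controls        score
#> 280 contaminant_01            0.04166667              0.8333333 0.0002442002
#> 281 contaminant_02            0.08333333              0.8333333 0.0008252284
clean <- prune_empty(remove_contaminants(sim$table, calls, sim$metadata))
index_hop_check(sim$table, sim$metadata, cfg$spike_taxon)$rate
#> [1] 0
```

Both injected contaminants are recovered (present in 5 of 6 negative
controls but almost no true samples) and no spike reads leak out of the
positive control. Per-replicate richness extrapolation and the
replicate-accumulation summary for extract E1 at a 5,000-read depth with
threshold 5:

```r
col <- clean$counts[, "PITS_E1_r01"]
cur <- richness_curve(col, seed = 1)
sprintf("n = %d reads, S_obs = %d, Chao1 asymptote = %.1f",
        sum(col), sum(col > 0), attr(cur, "s_hat"))
#> "n = 37089 reads, S_obs = 97, Chao1 asymptote = 107.1"

sub  <- clean[, grep("E1", colnames(clean$counts))]
cell <- vapply(colnames(sub$counts), function(r)
  as.integer(apply_min_read_threshold(
    rarefy(sub$counts[, r], 5000, seed = derive_seed(42, r)), 5)),
  integer(nrow(sub$counts)))
accumulation_curve(cell, B = 100, seed = 43)
#> replicate accumulation over 12 replicates; saturation at >12
#>   k mean_richness sd_richness
#> 1 1         33.60    3.265986
#> 2 2         42.88    3.111659
#> ...
occupancy_spectrum(cell)$singleton_fraction
#> [1] 0.3375
```

Each replicate sees ~34 taxa, twelve replicates together see 80, the
curve is still rising (saturation `>12`), and 34% of detected taxa appear
in exactly one replicate — rare taxa are recovered stochastically, which
is precisely the phenomenon the depth/threshold grid quantifies. The
config-driven orchestrator runs every stage and writes one TSV per result
family plus a JSON manifest:

```r
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = 42), "out/")
```

A thin command-line wrapper is installed at
`inst/scripts/replidepth.R` (`simulate` and `run` subcommands, YAML
configs).

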