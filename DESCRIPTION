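Package: replidepth
Title: PCR Replication and Read Sampling Depth Effects on Metabarcoding
    Diversity Estimates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the number of PCR replicates, the read
    sampling (rarefaction) depth, and per-replicate minimum read thresholds
    shape alpha- and beta-diversity estimates from environmental DNA
    metabarcoding taxon tables.  Implements prevalence-based contaminant
    identification against negative controls, a positive-control index-hop
    check, without-replacement rarefaction with repeated-draw averaging,
    observed/Shannon/Simpson indices, interpolated and extrapolated richness
    curves with bootstrap uncertainty (Hill number q = 0, Chao1-type
    asymptote), bootstrapped PCR-replicate accumulation curves with a
    saturation statistic, occupancy spectra and occupancy-abundance
    regression, local contributions to beta diversity (LCBD) with
    permutation tests, principal-coordinates ordination, and group
    dispersion testing around spatial medians with ANOVA and Tukey HSD.
    A Dirichlet-multinomial synthetic-experiment generator emulates the
    replicate/depth structure of a soil eDNA study (six extracts, 24 PCR
    replicates each, two markers) so the full pipeline runs with known
    ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
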