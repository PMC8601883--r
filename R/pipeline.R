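#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()].  Defaults follow
#' the emulated study design: rarefaction depths at every thousand reads
#' from 1,000 to 20,000, minimum read thresholds of 2, 5, and 10 applied
#' per PCR replicate, 25 rarefaction draws averaged per cell, alpha/beta
#' contrasts between 1,000 and 10,000 reads, a focal cell of 5,000 reads
#' with threshold 5 for accumulation/occupancy/LCBD, 100 accumulation
#' bootstraps, and 50 extrapolation bootstraps on 40 knots.
#'
#' @param synthetic a [synthetic_config()]; used unless `counts_paths` is
#'   given.
#' @param counts_paths,metadata_paths optional named character vectors
#'   (names = marker labels) of TSV paths; when supplied the pipeline runs
#'   on these tables instead of simulating.
#' @param spike_taxon positive-control taxon id for the index-hop check
#'   (defaults to the synthetic config's spike taxon).
#' @param depths,thresholds the rarefaction-grid axes.
#' @param rarefaction_repeats draws averaged per grid cell.
#' @param contrast_depths two depths for alpha/dispersion contrasts.
#' @param focal_depth,focal_threshold the cell used for accumulation,
#'   occupancy, and LCBD summaries.
#' @param saturation_depths depths at which saturation points are tabled.
#' @param accumulation_bootstraps shuffles per accumulation curve.
#' @param nboot,knots extrapolation-curve bootstrap count and knots.
#' @param n_perm permutations for LCBD and dispersion tests.
#' @param outlier_alpha level for LCBD outlier calls.
#' @param decontam_threshold prevalence-score flagging threshold.
#' @param seed master seed; every stage derives child seeds from it via
#'   [derive_seed()] so no stage consumes another's stream.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            counts_paths = NULL,
                            metadata_paths = NULL,
                            spike_taxon = NULL,
                            depths = seq(1000L, 20000L, by = 1000L),
                            thresholds = c(2L, 5L, 10L),
                            rarefaction_repeats = 25L,
                            contrast_depths = c(1000L, 10000L),
                            focal_depth = 5000L,
                            focal_threshold = 5L,
                            saturation_depths = c(5000L, 10000L),
                            accumulation_bootstraps = 100L,
                            nboot = 50L,
                            knots = 40L,
                            n_perm = 999L,
                            outlier_alpha = 0.05,
                            decontam_threshold = 0.1,
                            seed = 1L) {
  cfg <- list(synthetic = synthetic, counts_paths = counts_paths,
              metadata_paths = metadata_paths,
              spike_taxon = spike_taxon %||%
                (if (!is.null(synthetic)) synthetic$spike_taxon else NULL),
              depths = as.integer(depths), thresholds = as.integer(thresholds),
              rarefaction_repeats = as.integer(rarefaction_repeats),
              contrast_depths = as.integer(contrast_depths),
              focal_depth = as.integer(focal_depth),
              focal_threshold = as.integer(focal_threshold),
              saturation_depths = as.integer(saturation_depths),
              accumulation_bootstraps = as.integer(accumulation_bootstraps),
              nboot = as.integer(nboot), knots = as.integer(knots),
              n_perm = as.integer(n_perm), outlier_alpha = outlier_alpha,
              decontam_threshold = decontam_threshold,
              seed = as.integer(seed))
  stopifnot(length(cfg$contrast_depths) == 2,
            all(cfg$depths >= 1), all(cfg$thresholds >= 0))
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `synthetic` block mirrors [synthetic_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
         else synthetic_config()
  y$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), y))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One rarefied + thresholded snapshot of the sample table at a (d, t) cell;
# returns the retained columns only.
cell_table <- function(x, d, t, seed, marker) {
  totals <- replicate_depths(x)
  keep <- names(totals)[totals >= d]
  if (length(keep) == 0) return(NULL)
  counts <- vapply(keep, function(r)
    as.integer(apply_min_read_threshold(
      rarefy(x$counts[, r], d, seed = derive_seed(seed, marker, "cell", r, d, t)),
      t)), integer(nrow(x$counts)))
  counts <- matrix(counts, nrow = nrow(x$counts),
                   dimnames = list(rownames(x$counts), keep))
  taxon_table(counts)
}

#' Run the full replication/depth analysis pipeline
#'
#' Executes, per marker: (optional) simulation, prevalence-based
#' decontamination and the index-hop check, the rarefaction depth-by-
#' threshold grid, per-replicate alpha indices with depth-contrast tests,
#' extrapolated richness with IQR outlier calls per extract, bootstrapped
#' replicate-accumulation curves with saturation points, occupancy spectra
#' and the occupancy-abundance regression, LCBD with permutation outlier
#' calls and chi-square contrasts of outlier counts across depths and
#' thresholds, and within-extract dispersion contrasts between the two
#' contrast depths.  One TSV is written per result family plus a JSON run
#' manifest; rerunning with the same configuration reproduces every
#' output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of all result objects, one element per marker.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # ---- input stage -------------------------------------------------------
  if (!is.null(config$counts_paths)) {
    markers <- names(config$counts_paths)
    data <- lapply(markers, function(mk) list(
      table = read_taxon_table(config$counts_paths[[mk]]),
      metadata = read_replicate_metadata(config$metadata_paths[[mk]]),
      truth = NULL))
    names(data) <- markers
  } else {
    data <- simulate_experiment(config$synthetic)
    markers <- names(data)
  }

  results <- list()
  manifest_stages <- list()
  for (mk in markers) {
    tab <- data[[mk]]$table
    meta <- align_metadata(tab, data[[mk]]$metadata)
    res <- list(marker = mk)

    # ---- decontamination + index hop ------------------------------------
    has_controls <- any(meta$sample_type %in%
                          c("extraction_control", "pcr_control"))
    if (has_controls) {
      calls <- prevalence_scores(tab, meta, threshold = config$decontam_threshold)
      res$decontam_calls <- calls
      clean <- remove_contaminants(tab, calls, meta,
                                   threshold = config$decontam_threshold)
    } else {
      clean <- tab[, meta$sample_type == "sample"]
    }
    if (!is.null(config$spike_taxon) &&
        config$spike_taxon %in% rownames(tab$counts) &&
        any(meta$sample_type == "positive_control")) {
      res$index_hop <- index_hop_check(tab, meta, config$spike_taxon)
      clean <- clean[setdiff(rownames(clean$counts), config$spike_taxon), ]
    }
    clean <- prune_empty(clean)
    res$clean_table <- clean
    meta_s <- meta[match(colnames(clean$counts), meta$replicate_id), ]
    extract_of <- setNames(meta_s$extract_id, meta_s$replicate_id)
    extracts <- unique(meta_s$extract_id)

    # ---- rarefaction grid -----------------------------------------------
    gr <- rarefaction_grid(clean, config$depths, config$thresholds,
                           R = config$rarefaction_repeats,
                           seed = derive_seed(seed, mk, "grid"))
    res$grid <- gr$grid
    res$retained <- gr$retained
    for (i in seq_len(nrow(gr$retained)))
      message(sprintf("[%s] depth %d: %d replicates retained", mk,
                      gr$retained$depth[i], gr$retained$n_retained[i]))

    # ---- alpha indices + depth contrasts --------------------------------
    alpha_depths <- sort(unique(c(config$contrast_depths, config$focal_depth)))
    totals <- replicate_depths(clean)
    arec <- list()
    for (d in alpha_depths) for (t in config$thresholds) {
      for (r in colnames(clean$counts)) {
        if (totals[[r]] < d) next
        y <- apply_min_read_threshold(
          rarefy(clean$counts[, r], d,
                 seed = derive_seed(seed, mk, "alpha", r, d, t)), t)
        ai <- alpha_indices(y)
        arec[[length(arec) + 1L]] <- data.frame(
          replicate_id = r, extract_id = extract_of[[r]], depth = d,
          threshold = t, observed = ai$observed, shannon = ai$shannon,
          simpson = ai$simpson, stringsAsFactors = FALSE)
      }
    }
    res$alpha <- do.call(rbind, arec)
    if (!is.null(res$alpha)) {
      foc <- res$alpha[res$alpha$threshold == config$focal_threshold, ]
      res$depth_contrasts <- tryCatch(
        suppressWarnings(depth_contrast_tests(
          foc, config$contrast_depths[1], config$contrast_depths[2])),
        error = function(e) NULL)
    }

    # ---- extrapolated richness + outliers -------------------------------
    ext <- lapply(colnames(clean$counts), function(r) {
      cur <- richness_curve(clean$counts[, r], knots = config$knots,
                            nboot = config$nboot,
                            seed = derive_seed(seed, mk, "extrap", r))
      data.frame(replicate_id = r, extract_id = extract_of[[r]],
                 n = totals[[r]], s_obs = sum(clean$counts[, r] > 0),
                 s_hat = attr(cur, "s_hat"),
                 s_double = cur$richness[nrow(cur)],
                 se_double = cur$se[nrow(cur)], stringsAsFactors = FALSE)
    })
    ext <- do.call(rbind, ext)
    ext$outlier <- FALSE
    for (ex in extracts) {
      idx <- which(ext$extract_id == ex)
      if (length(idx) >= 4)
        ext$outlier[idx] <- iqr_outliers(ext$s_hat[idx])$outlier
    }
    res$extrapolation <- ext

    # ---- replicate accumulation -----------------------------------------
    acc <- list()
    for (ex in extracts) for (d in config$saturation_depths)
      for (t in config$thresholds) {
        sub <- clean[, names(extract_of)[extract_of == ex]]
        cell <- cell_table(sub, d, t, seed, mk)
        if (is.null(cell)) next
        ac <- accumulation_curve(cell, B = config$accumulation_bootstraps,
                                 seed = derive_seed(seed, mk, "accum", ex, d, t))
        acc[[length(acc) + 1L]] <- data.frame(
          extract_id = ex, depth = d, threshold = t, retained = ac$K,
          saturation = ac$saturation_label,
          pooled_richness = ac$curve$mean_richness[ac$K],
          stringsAsFactors = FALSE)
      }
    res$saturation <- do.call(rbind, acc)

    # ---- occupancy at the focal cell ------------------------------------
    occ <- list()
    for (ex in extracts) {
      sub <- clean[, names(extract_of)[extract_of == ex]]
      cell <- cell_table(sub, config$focal_depth, config$focal_threshold,
                         seed, mk)
      if (is.null(cell)) next
      rec <- occupancy_records(cell)
      if (nrow(rec) == 0) next
      rec$extract_id <- ex
      rec$retained <- ncol(cell$counts)
      occ[[length(occ) + 1L]] <- rec
    }
    occ <- do.call(rbind, occ)
    res$occupancy <- occ
    res$occupancy_fit <- if (!is.null(occ) && nrow(occ) >= 3)
      occupancy_abundance_fit(occ) else NULL
    res$singleton_fraction <- if (!is.null(occ))
      vapply(split(occ, occ$extract_id), function(rr)
        occupancy_spectrum(rr, K = rr$retained[1])$singleton_fraction, 0)
    else NULL

    # ---- LCBD + outlier-count chi-square contrasts ----------------------
    lcbd_cells <- unique(rbind(
      data.frame(depth = alpha_depths, threshold = config$focal_threshold),
      data.frame(depth = config$focal_depth, threshold = config$thresholds)))
    lres <- list()
    for (i in seq_len(nrow(lcbd_cells))) {
      d <- lcbd_cells$depth[i]; t <- lcbd_cells$threshold[i]
      cell <- cell_table(clean, d, t, seed, mk)
      if (is.null(cell) || ncol(cell$counts) < 3) next
      lr <- lcbd(cell, n_perm = config$n_perm, alpha = config$outlier_alpha,
                 seed = derive_seed(seed, mk, "lcbd", d, t))
      ltab <- lr$table
      ltab$extract_id <- extract_of[ltab$replicate_id]
      ltab$depth <- d; ltab$threshold <- t
      lres[[length(lres) + 1L]] <- ltab
    }
    res$lcbd <- do.call(rbind, lres)
    res$lcbd_tests <- lcbd_outlier_tests(res$lcbd, config)

    # ---- dispersion contrast between the two depths ---------------------
    disp <- list()
    d1 <- config$contrast_depths[1]; d2 <- config$contrast_depths[2]
    for (ex in extracts) {
      sub <- clean[, names(extract_of)[extract_of == ex]]
      keep <- replicate_depths(sub) >= d2
      if (sum(keep) < 2) next
      sub <- sub[, keep]
      c1 <- cell_table(sub, d1, config$focal_threshold, seed, paste0(mk, "_lo"))
      c2 <- cell_table(sub, d2, config$focal_threshold, seed, paste0(mk, "_hi"))
      both <- cbind(c1$counts, c2$counts)
      colnames(both) <- c(paste0(colnames(c1$counts), "@", d1),
                          paste0(colnames(c2$counts), "@", d2))
      D <- jaccard_distance(both)
      bd <- beta_dispersion(D, rep(c(d1, d2), each = sum(keep)),
                            n_perm = config$n_perm,
                            seed = derive_seed(seed, mk, "disp", ex))
      disp[[length(disp) + 1L]] <- data.frame(
        extract_id = ex, F = bd$F, p_anova = bd$p_anova,
        p_permutation = bd$p_permutation,
        mean_disp_low = unname(bd$group_means[as.character(d1)]),
        mean_disp_high = unname(bd$group_means[as.character(d2)]),
        stringsAsFactors = FALSE)
    }
    res$dispersion <- do.call(rbind, disp)

    # ---- write this marker's outputs ------------------------------------
    pfx <- function(name) file.path(out_dir, sprintf("%s_%s.tsv", mk, name))
    if (!is.null(res$decontam_calls)) write_tsv(res$decontam_calls, pfx("decontam"))
    write_tsv(res$grid, pfx("grid"))
    write_tsv(res$retained, pfx("retained"))
    if (!is.null(res$alpha)) write_tsv(res$alpha, pfx("alpha"))
    if (!is.null(res$depth_contrasts))
      write_tsv(res$depth_contrasts, pfx("contrasts"))
    write_tsv(res$extrapolation, pfx("extrapolation"))
    if (!is.null(res$saturation)) write_tsv(res$saturation, pfx("saturation"))
    if (!is.null(res$occupancy)) write_tsv(res$occupancy, pfx("occupancy"))
    if (!is.null(res$lcbd)) write_tsv(res$lcbd, pfx("lcbd"))
    if (!is.null(res$dispersion)) write_tsv(res$dispersion, pfx("dispersion"))
    manifest_stages[[mk]] <- list(
      n_taxa_input = nrow(tab$counts), n_taxa_clean = nrow(clean$counts),
      n_replicates = ncol(clean$counts),
      retained = setNames(as.list(gr$retained$n_retained),
                          as.character(gr$retained$depth)),
      contaminants_flagged = if (has_controls)
        sum(res$decontam_calls$is_contaminant) else NA,
      hop_rate = if (!is.null(res$index_hop)) res$index_hop$rate else NA)
    results[[mk]] <- res
  }

  manifest <- list(package = "replidepth",
                   version = as.character(utils::packageVersion("replidepth")),
                   seed = seed,
                   parameters = config_to_list(config),
                   stages = manifest_stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(results)
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) out$synthetic <- unclass(out$synthetic)
  out
}

# Chi-square contrasts of LCBD outlier counts across depths, thresholds,
# and extracts (outlier vs non-outlier columns).
lcbd_outlier_tests <- function(ltab, config) {
  if (is.null(ltab) || nrow(ltab) == 0) return(NULL)
  mk_test <- function(sub, by) {
    counts <- table(factor(sub$outlier, levels = c(FALSE, TRUE)), sub[[by]])
    out <- tryCatch(outlier_count_test(as.matrix(counts)),
                    error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(contrast = by, statistic = out$statistic, df = out$df,
               p_value = out$p_value, stringsAsFactors = FALSE)
  }
  by_depth <- mk_test(ltab[ltab$threshold == config$focal_threshold, ], "depth")
  by_thresh <- mk_test(ltab[ltab$depth == config$focal_depth, ], "threshold")
  by_extract <- mk_test(ltab[ltab$threshold == config$focal_threshold &
                               ltab$depth == config$focal_depth, ], "extract_id")
  do.call(rbind, Filter(Negate(is.null),
                        list(by_depth, by_thresh, by_extract)))
}
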