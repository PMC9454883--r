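#' Run the simulator and write a panel bundle
#'
#' Generates a truth panel, a density-masked target and an error-injected
#' imputed panel from a [simulation_config()], writing `truth.vcf`,
#' `masked.vcf`, `imputed.vcf`, a per-marker `info_scores.tsv` (computed
#' from the emitted posteriors), optionally the full `posteriors.tsv`, and
#' a JSON sidecar `config.json` recording every configuration parameter.
#' Identical config and seed produce byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory, created if absent.
#' @param write_posteriors also write the long-format posterior table
#'   (sample, marker, three probabilities); off by default as it is by far
#'   the largest output.
#' @return Invisibly, the [simulate_panel_set()] result with a `paths`
#'   element added.
#' @export
run_simulation <- function(config = simulation_config(), out_dir,
                           write_posteriors = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel_set(config)
  paths <- list(truth = file.path(out_dir, "truth.vcf"),
                masked = file.path(out_dir, "masked.vcf"),
                imputed = file.path(out_dir, "imputed.vcf"),
                info = file.path(out_dir, "info_scores.tsv"),
                config = file.path(out_dir, "config.json"))
  write_genotypes(sim$truth, paths$truth)
  write_genotypes(sim$masked, paths$masked)
  write_genotypes(sim$imputed, paths$imputed)
  info <- marker_info_scores(sim$posteriors)
  utils::write.table(
    data.frame(chr = sim$truth$map$chr, pos = sim$truth$map$pos,
               id = sim$truth$map$id, info = info),
    paths$info, sep = "\t", quote = FALSE, row.names = FALSE)
  if (write_posteriors) {
    paths$posteriors <- file.path(out_dir, "posteriors.tsv")
    n <- dim(sim$posteriors)[1L]; m <- dim(sim$posteriors)[2L]
    utils::write.table(
      data.frame(sample = rep(sim$truth$samples, times = m),
                 id = rep(sim$truth$map$id, each = n),
                 p_homref = as.vector(sim$posteriors[, , 1L]),
                 p_het = as.vector(sim$posteriors[, , 2L]),
                 p_homalt = as.vector(sim$posteriors[, , 3L])),
      paths$posteriors, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(config)
  cfg$error_model <- list(
    transition = unclass(cfg$error_model$transition),
    maf_slope = cfg$error_model$maf_slope,
    bad_regions = cfg$error_model$bad_regions,
    end_gradient = cfg$error_model$end_gradient)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  sim$paths <- paths
  invisible(sim)
}

#' Evaluate an imputed panel against a truth panel
#'
#' The full evaluation pipeline: read both VCFs, harmonize the imputed
#' panel's allele coding to the truth map, intersect to shared samples and
#' markers, then compute every accuracy statistic (overall/per-sample/
#' per-SNP concordance and correlation, genotype confusion, binned
#' concordance, allele-frequency correlation, fixed-SNP report), optionally
#' the GRM comparison, and the poorly-imputed-region scan over the per-SNP
#' concordance track. Results are computed in full before anything is
#' written, so a failure leaves no partial bundle.
#'
#' @param truth_path,imputed_path VCF paths (or `genotype_matrix` objects).
#' @param out_dir output directory for the report bundle; `NULL` skips
#'   writing and just returns the results.
#' @param scan a [scan_parameters()].
#' @param bin_width allele-frequency bin width.
#' @param grm compute the GRM comparison (can be slow on large panels).
#' @param info optional per-marker info scores aligned with the truth map
#'   (or a path to a `info_scores.tsv` as written by [run_simulation()]).
#' @param info_cutoff cutoff for [info_filter_evaluation()].
#' @return Invisibly, a list with all result objects (`concordance`,
#'   `correlation`, `confusion`, `bins`, `af_correlation`, `fixed`,
#'   `grm_ss`, `scan`, `harmonization`, `info_eval`, `summary`).
#' @export
run_evaluation <- function(truth_path, imputed_path, out_dir = NULL,
                           scan = scan_parameters(), bin_width = 0.01,
                           grm = TRUE, info = NULL, info_cutoff = 0.6) {
  truth <- if (inherits(truth_path, "genotype_matrix")) truth_path
           else read_genotypes(truth_path)
  imputed <- if (inherits(imputed_path, "genotype_matrix")) imputed_path
             else read_genotypes(imputed_path)
  harm <- harmonize_markers(imputed, truth$map)
  pair <- intersect_panels(truth, harm$matrix)

  conc <- concordance(pair)
  corr <- dosage_correlation(pair)
  conf <- genotype_confusion(pair)
  bins <- af_binned_concordance(conc$per_snp, bin_width)
  afr <- allele_frequency_correlation(pair)
  fixed <- fixed_snp_report(pair)

  grm_res <- NULL
  if (isTRUE(grm)) {
    g_t <- compute_grm(pair$truth)
    g_i <- compute_grm(pair$imputed, freqs = alt_freq(pair$truth))
    grm_res <- list(truth = g_t, imputed = g_i,
                    ss_deviation = grm_ss_deviation(g_t, g_i),
                    pca_truth = grm_pca(g_t, min(2L, n_samples(pair$truth))),
                    pca_imputed = grm_pca(g_i, min(2L, n_samples(pair$truth))))
  }

  ps <- conc$per_snp[!is.na(conc$per_snp$cr), , drop = FALSE]
  track <- accuracy_track(ps$chr, ps$pos, ps$cr)
  if (all(track$value == 1)) {
    # a perfectly concordant panel has no poorly imputed regions, even
    # though a constant track would flag everything under the <= rule
    scan_res <- list(smoothed = track, cutoff = 1,
                     flagged = track[0, c("chr", "pos")],
                     regions = merge_regions(data.frame(chr = character(0),
                                                        pos = numeric(0)),
                                             scan),
                     params = scan)
  } else {
    scan_res <- scan_regions(track, scan)
  }

  info_eval <- NULL
  if (!is.null(info)) {
    if (is.character(info)) {
      it <- utils::read.table(info, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      it$chr <- as.character(it$chr)
      info <- it$info[match(marker_key(pair$truth$map),
                            paste(it$chr, it$pos, sep = ":"))]
    }
    info_eval <- info_filter_evaluation(info, conc$per_snp, info_cutoff)
  }

  summary <- list(
    n_samples = n_samples(pair$truth),
    n_markers = n_markers(pair$truth),
    overall_cr = conc$overall,
    mean_sample_r = unname(corr$summary$sample_r["mean"]),
    mean_snp_r = corr$summary$snp_r_mean,
    n_snp_r_undefined = corr$summary$n_snp_undefined,
    het_error_pct = conf$het_error_pct,
    af_correlation = afr,
    frac_snps_cr_below_0.9 = conc$summary$frac_snps_below_0.9,
    monomorphic_pct = fixed$monomorphic_pct,
    spurious_fraction = fixed$spurious_fraction,
    grm_ss_deviation = if (is.null(grm_res)) NULL else grm_res$ss_deviation,
    region_cutoff = scan_res$cutoff,
    n_regions = nrow(scan_res$regions),
    harmonization = stats::setNames(as.list(harm$report$n),
                                    harm$report$category))
  res <- list(pair = pair, concordance = conc, correlation = corr,
              confusion = conf, bins = bins, af_correlation = afr,
              fixed = fixed, grm = grm_res, scan = scan_res,
              harmonization = harm$report, info_eval = info_eval,
              summary = summary)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  invisible(res)
}

#' Write an evaluation report bundle
#'
#' Emits `summary.json` plus tab-separated tables: per-sample and per-SNP
#' accuracies, the genotype confusion table (counts and row percentages),
#' frequency-bin concordances, the harmonization report and the region
#' table.
#'
#' @param res result list from [run_evaluation()].
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the directory path.
#' @export
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  per_sample <- merge(res$concordance$per_sample, res$correlation$per_sample,
                      by = "sample", sort = FALSE)
  per_snp <- cbind(res$concordance$per_snp,
                   r = res$correlation$per_snp$r)
  tsv(per_sample, "per_sample.tsv")
  tsv(per_snp, "per_snp.tsv")
  conf <- data.frame(true = rownames(res$confusion$counts),
                     res$confusion$counts,
                     res$confusion$row_pct, check.names = FALSE)
  names(conf) <- c("true", paste0(colnames(res$confusion$counts), "_n"),
                   paste0(colnames(res$confusion$counts), "_pct"))
  tsv(conf, "confusion.tsv")
  tsv(res$bins, "bins.tsv")
  tsv(as.data.frame(res$harmonization), "harmonization.tsv")
  write_region_table(res$scan$regions, file.path(out_dir, "regions.tsv"),
                     comments = sprintf(
                       "window=%d percentile=%g max_gap_bp=%g min_snps=%d cutoff=%.6g",
                       res$scan$params$window, res$scan$params$percentile,
                       res$scan$params$max_gap_bp, res$scan$params$min_snps,
                       res$scan$cutoff))
  summ <- res$summary
  summ$fixed_snp_report <- unclass(res$fixed)
  if (!is.null(res$info_eval)) summ$info_eval <- unclass(res$info_eval)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}

#' Scan a per-marker accuracy table file for poorly imputed regions
#'
#' Reads a tab-separated accuracy table with columns `chr`, `pos`, `cr`
#' (extra columns ignored), runs [scan_regions()] and writes the region
#' table with the scan parameters echoed as header comments.
#'
#' @param track_path input TSV path.
#' @param out_path output region-table path.
#' @param params a [scan_parameters()].
#' @return Invisibly, the scan result list.
#' @export
run_region_scan <- function(track_path, out_path,
                            params = scan_parameters()) {
  d <- utils::read.table(track_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$chr <- as.character(d$chr)
  need <- c("chr", "pos", "cr")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("run_region_scan: missing column(s): ", paste(miss, collapse = ", "))
  d <- d[!is.na(d$cr), , drop = FALSE]
  track <- accuracy_track(d$chr, d$pos, d$cr)
  res <- scan_regions(track, params)
  write_region_table(res$regions, out_path, comments = sprintf(
    "window=%d percentile=%g max_gap_bp=%g min_snps=%d cutoff=%.6g",
    params$window, params$percentile, params$max_gap_bp, params$min_snps,
    res$cutoff))
  invisible(res)
}

#' Reference-panel composition experiment
#'
#' Simulates a target population, imputes it with the naive
#' nearest-haplotype imputer from four reference panels — within-population
#' haplotypes, an independently simulated diverged population, both
#' combined, and the diverged pool plus a small within-population subset —
#' and reports the overall concordance rate of each, per replicate seed.
#' The expected pattern mirrors what real multi-breed imputation studies
#' find: a related within-population reference beats a much larger
#' diverged reference, combining adds essentially nothing over the
#' within-population panel, and adding even a small related subset to a
#' diverged reference recovers a large share of the lost accuracy.
#'
#' @param seeds integer vector of replicate seeds (>= 3 recommended).
#' @param markers markers on the single simulated chromosome.
#' @param n_within within-population founder haplotypes.
#' @param n_diverged diverged-population haplotypes.
#' @param n_small size of the small within-population subset.
#' @param n_targets target sample count.
#' @param keep_fraction low-density mask fraction.
#' @param switch_rate mosaic switch rate.
#' @param window imputer window size in markers.
#' @return Matrix (replicates x 4) of overall concordance rates with
#'   columns `within`, `combined`, `diverged`, `diverged_plus_small`.
#' @export
reference_composition_experiment <- function(seeds = 1:5, markers = 800L,
                                             n_within = 40L,
                                             n_diverged = 240L,
                                             n_small = 10L, n_targets = 30L,
                                             keep_fraction = 0.10,
                                             switch_rate = 0.005,
                                             window = 400L) {
  one <- function(seed) {
    cfg <- simulation_config(n_chr = 1, markers_per_chr = markers,
                             n_founder_haps = n_within,
                             monomorphic_fraction = 0,
                             af_shape1 = 1, af_shape2 = 1,
                             switch_rate = switch_rate, seed = seed)
    popA <- simulate_founder_haplotypes(cfg)
    cfgB <- cfg
    cfgB$n_founder_haps <- as.integer(n_diverged)
    popB <- simulate_founder_haplotypes(cfgB, map = popA$map,
                                        seed = seed + 1000L)
    desc <- simulate_descendants(popA, n_targets, switch_rate,
                                 seed = seed + 2L)
    masked <- mask_to_density(desc$matrix, keep_fraction, seed = seed + 3L)
    hs <- function(h) structure(list(haps = h, map = popA$map,
                                     freq = popA$freq),
                                class = "haplotype_set")
    # diverged haplotypes first, so matching ties favour them: the
    # combined panel can only lose (never gain) relative to within-only
    refs <- list(
      within = popA,
      combined = hs(rbind(popB$haps, popA$haps)),
      diverged = popB,
      diverged_plus_small = hs(rbind(popB$haps,
                                     popA$haps[seq_len(n_small), , drop = FALSE])))
    vapply(refs, function(r) {
      imp <- naive_reference_imputer(masked, r, window = window)
      concordance(panel_pair(desc$matrix, imp))$overall
    }, numeric(1))
  }
  t(vapply(seeds, one, numeric(4)))
}
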