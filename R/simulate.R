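#' Genotype error model
#'
#' Describes how an "imputed" panel deviates from the truth. The core is a
#' 3x3 genotype transition matrix (rows = true dosage 0/1/2, columns =
#' emitted dosage) whose rows sum to 1. Around it, three optional modifiers
#' rescale the off-diagonal (error) mass of the row actually used at a
#' marker, after which the row is renormalized:
#'
#' * `maf_slope`: multiplier `1 + maf_slope * maf / 0.5`, so common variants
#'   are imputed worse than rare ones, the pattern seen in real panels;
#' * `bad_regions`: planted genomic intervals whose markers get their error
#'   mass multiplied by `multiplier`;
#' * `end_gradient`: extra error towards chromosome ends, multiplier
#'   `1 + strength * exp(-distance_to_nearest_end / scale_bp)`.
#'
#' The default transition matrix reflects genotype-class concordances
#' typical of within-breed sequence imputation with a small reference
#' panel: about 94/90/98 percent correct for hom-REF/het/hom-ALT.
#'
#' @param transition 3x3 row-stochastic matrix.
#' @param maf_slope non-negative scalar; 0 disables MAF dependence.
#' @param bad_regions `data.frame(chr, start, end, multiplier)` or `NULL`.
#' @param end_gradient `list(strength =, scale_bp =)` or `NULL`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(transition = matrix(c(0.9369, 0.0591, 0.0040,
                                              0.0247, 0.8953, 0.0800,
                                              0.0004, 0.0193, 0.9803),
                                            nrow = 3, byrow = TRUE),
                        maf_slope = 0,
                        bad_regions = NULL,
                        end_gradient = NULL) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(3L, 3L)))
    stop("error_model: transition must be 3x3")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("error_model: transition rows must be non-negative and sum to 1")
  if (maf_slope < 0) stop("error_model: maf_slope must be >= 0")
  if (!is.null(bad_regions)) {
    bad_regions <- as.data.frame(bad_regions)
    stopifnot(all(c("chr", "start", "end", "multiplier") %in%
                    names(bad_regions)))
    bad_regions$chr <- as.character(bad_regions$chr)
  }
  if (!is.null(end_gradient))
    stopifnot(is.numeric(end_gradient$strength),
              is.numeric(end_gradient$scale_bp), end_gradient$scale_bp > 0)
  structure(list(transition = transition, maf_slope = maf_slope,
                 bad_regions = bad_regions, end_gradient = end_gradient),
            class = "error_model")
}

#' Identity (error-free) model
#' @return An `error_model` whose transition matrix is the identity.
#' @export
identity_error_model <- function() error_model(diag(3))

#' Simulation configuration
#'
#' Parameters of the synthetic genotype study: a multi-chromosome marker
#' map, a founder haplotype pool, mosaic descendants, a low-density mask
#' and an imputation error model. With the seed fixed, every downstream
#' operation is reproducible bit for bit.
#'
#' Defaults describe a compact but structured cattle-like study: 3
#' autosomes of 100 Mb carrying 2,000 markers each, 60 founder haplotypes,
#' 136 evaluation samples, a U-shaped allele-frequency spectrum
#' (Beta(0.3, 0.3)) so both tails of the 0.01-wide frequency bins are
#' populated, a third of markers fixed (monomorphic), and spurious
#' segregation injected at 31% of fixed markers with mean imputed MAF 0.012.
#'
#' @param n_chr number of chromosomes.
#' @param chr_length_bp chromosome length in base pairs (recycled).
#' @param markers_per_chr markers per chromosome (recycled).
#' @param n_founder_haps founder haplotype count.
#' @param n_samples descendant sample count.
#' @param af_shape1,af_shape2 Beta parameters of the ALT-frequency spectrum.
#' @param monomorphic_fraction per-marker probability of being forced fixed
#'   for the ALT allele (frequency 0).
#' @param switch_rate per-marker probability that a descendant haplotype
#'   switches founder template (geometric segment lengths).
#' @param missing_rate per-call probability of a missing genotype in truth.
#' @param mask_keep_fraction fraction of markers retained by the
#'   low-density mask.
#' @param error_model an [error_model()].
#' @param spurious_rate fraction of truth-monomorphic markers that receive
#'   spurious segregating calls in the imputed panel.
#' @param spurious_freq_scale mean imputed MAF of those markers.
#' @param seed integer random seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_chr = 3,
                              chr_length_bp = 1e8,
                              markers_per_chr = 2000,
                              n_founder_haps = 60,
                              n_samples = 136,
                              af_shape1 = 0.3,
                              af_shape2 = 0.3,
                              monomorphic_fraction = 0.33,
                              switch_rate = 0.01,
                              missing_rate = 0,
                              mask_keep_fraction = 0.1,
                              error_model = imputeval::error_model(),
                              spurious_rate = 0.31,
                              spurious_freq_scale = 0.012,
                              seed = 1L) {
  cfg <- list(n_chr = as.integer(n_chr),
              chr_length_bp = rep_len(as.numeric(chr_length_bp), n_chr),
              markers_per_chr = rep_len(as.integer(markers_per_chr), n_chr),
              n_founder_haps = as.integer(n_founder_haps),
              n_samples = as.integer(n_samples),
              af_shape1 = af_shape1, af_shape2 = af_shape2,
              monomorphic_fraction = monomorphic_fraction,
              switch_rate = switch_rate,
              missing_rate = missing_rate,
              mask_keep_fraction = mask_keep_fraction,
              error_model = error_model,
              spurious_rate = spurious_rate,
              spurious_freq_scale = spurious_freq_scale,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chr > 0, all(chr_length_bp > 0), all(markers_per_chr > 0),
              n_founder_haps > 0, n_samples > 0,
              af_shape1 > 0, af_shape2 > 0,
              monomorphic_fraction >= 0, monomorphic_fraction <= 1,
              switch_rate >= 0, switch_rate <= 1,
              missing_rate >= 0, missing_rate <= 1,
              mask_keep_fraction > 0, mask_keep_fraction <= 1,
              spurious_rate >= 0, spurious_rate <= 1,
              spurious_freq_scale >= 0)
  })
  if (!inherits(cfg$error_model, "error_model"))
    stop("simulation_config: error_model must be an error_model object")
  structure(cfg, class = "simulation_config")
}

#' Simulate founder haplotypes
#'
#' Draws per-marker ALT frequencies from the configured Beta spectrum,
#' forces a configured fraction of markers monomorphic (frequency 0), and
#' samples binary founder haplotypes independently per marker given the
#' frequency. Marker positions are sampled uniformly without replacement
#' along each chromosome.
#'
#' @param config a [simulation_config()].
#' @param map reuse an existing [marker_map()] instead of sampling
#'   positions (used to simulate a diverged population on the same markers).
#' @param seed overrides `config$seed` when given.
#' @return An object of class `haplotype_set`: list with binary matrix
#'   `haps` (haplotypes x markers), `map`, and the per-marker `freq` used.
#' @export
simulate_founder_haplotypes <- function(config, map = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  if (is.null(map)) {
    maps <- lapply(seq_len(config$n_chr), function(ch) {
      m <- config$markers_per_chr[ch]
      len <- config$chr_length_bp[ch]
      pos <- sort(sample.int(len, m))
      # draw non-complementary REF/ALT pairs so simulated panels carry no
      # strand-ambiguous (A/T, C/G) markers and survive harmonization whole
      bases <- c("A", "C", "G", "T")
      compl <- c(A = "T", C = "G", G = "C", T = "A")
      ref <- sample(bases, m, replace = TRUE)
      alt <- vapply(ref, function(r)
        sample(setdiff(bases, c(r, compl[[r]])), 1L), character(1))
      data.frame(chr = as.character(ch), pos = pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    })
    md <- do.call(rbind, maps)
    map <- marker_map(md$chr, md$pos, ref = md$ref, alt = md$alt)
  }
  m <- nrow(map)
  freq <- stats::rbeta(m, config$af_shape1, config$af_shape2)
  if (all(freq == 0)) stop("simulate_founder_haplotypes: degenerate spectrum")
  mono <- stats::runif(m) < config$monomorphic_fraction
  freq[mono] <- 0
  H <- config$n_founder_haps
  haps <- matrix(stats::rbinom(H * m, 1L, rep(freq, each = H)), nrow = H)
  structure(list(haps = haps, map = map, freq = freq),
            class = "haplotype_set")
}

#' Simulate mosaic descendants from a founder haplotype pool
#'
#' Each descendant carries two haplotypes, each a mosaic of founder
#' haplotypes: along every chromosome the template switches to a different
#' founder with probability `switch_rate` per marker interval, giving
#' geometric segment lengths. Genotype dosage is the sum of the two
#' haplotype alleles.
#'
#' @param founders a `haplotype_set`.
#' @param n_samples number of descendants.
#' @param switch_rate per-marker template switch probability.
#' @param seed integer seed.
#' @param missing_rate per-call probability of masking a genotype to `NA`.
#' @return List with `matrix` (a `genotype_matrix`) and `haps`
#'   (a `haplotype_set` of the 2 x n descendant haplotypes).
#' @export
simulate_descendants <- function(founders, n_samples, switch_rate,
                                 seed = 1L, missing_rate = 0) {
  if (nrow(founders$haps) == 0L) stop("simulate_descendants: empty founder set")
  if (switch_rate < 0 || switch_rate > 1)
    stop("simulate_descendants: switch_rate must lie in [0, 1]")
  set.seed(as.integer(seed))
  map <- founders$map
  m <- nrow(map)
  H <- nrow(founders$haps)
  chr_idx <- split(seq_len(m), factor(map$chr, unique(map$chr)))
  n_haps <- 2L * n_samples
  haps <- matrix(0L, n_haps, m)
  for (idx in chr_idx) {
    mc <- length(idx)
    for (h in seq_len(n_haps)) {
      src <- integer(mc)
      sw_at <- if (mc > 1L) which(stats::runif(mc - 1L) < switch_rate) else integer(0)
      bounds <- c(1L, sw_at + 1L, mc + 1L)    # segment starts (+ sentinel)
      cur <- sample.int(H, 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        if (b > 1L) cur <- resample_other(H, cur)
        src[bounds[b]:(bounds[b + 1L] - 1L)] <- cur
      }
      haps[h, idx] <- founders$haps[cbind(src, idx)]
    }
  }
  geno <- haps[seq(1L, n_haps, 2L), , drop = FALSE] +
    haps[seq(2L, n_haps, 2L), , drop = FALSE]
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  gm <- genotype_matrix(geno, paste0("S", seq_len(n_samples)), map)
  list(matrix = gm,
       haps = structure(list(haps = haps, map = map, freq = founders$freq),
                        class = "haplotype_set"))
}

resample_other <- function(H, cur) {
  if (H == 1L) return(cur)
  k <- sample.int(H - 1L, 1L)
  if (k >= cur) k + 1L else k
}

#' Mask a panel down to a lower marker density
#'
#' Retains a uniformly sampled, order-preserving subset of
#' `round(keep_fraction * m)` markers, emulating the nesting of commercial
#' SNP arrays inside a sequence panel. Masks compose: masking a masked
#' panel again keeps `round(round(m a) b)` markers.
#'
#' @param x a `genotype_matrix`.
#' @param keep_fraction fraction of markers to keep, in (0, 1].
#' @param seed integer seed.
#' @return The masked `genotype_matrix`; the sample set is unchanged.
#' @export
mask_to_density <- function(x, keep_fraction, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("mask_to_density: keep_fraction must lie in (0, 1]")
  m <- n_markers(x)
  k <- round(keep_fraction * m)
  if (k < 1L) stop("mask_to_density: zero markers retained")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(m, k))
  subset_markers(x, keep)
}

# per-marker off-diagonal multiplier from the model's modifiers
error_multipliers <- function(map, freq, model, chr_lengths = NULL) {
  m <- nrow(map)
  maf <- pmin(freq, 1 - freq)
  mult <- 1 + model$maf_slope * maf / 0.5
  if (!is.null(model$bad_regions)) {
    for (r in seq_len(nrow(model$bad_regions))) {
      reg <- model$bad_regions[r, ]
      sel <- map$chr == reg$chr & map$pos >= reg$start & map$pos <= reg$end
      if (!any(map$chr == reg$chr))
        stop("error_model: planted region on absent chromosome ", reg$chr)
      if (!any(sel))
        stop("error_model: planted region ", reg$chr, ":", reg$start, "-",
             reg$end, " contains no simulated markers")
      mult[sel] <- mult[sel] * reg$multiplier
    }
  }
  if (!is.null(model$end_gradient)) {
    if (is.null(chr_lengths)) {
      chr_lengths <- tapply(map$pos, map$chr, max)
    }
    len <- as.numeric(chr_lengths[map$chr])
    if (any(is.na(len) | map$pos > len))
      stop("error_model: marker position outside stated chromosome length")
    d <- pmin(map$pos, len - map$pos)
    mult <- mult * (1 + model$end_gradient$strength *
                      exp(-d / model$end_gradient$scale_bp))
  }
  mult
}

#' Inject genotype errors into a truth panel
#'
#' Emits, for every non-missing call, a genotype drawn from the row of the
#' locally modified transition matrix for the call's true genotype. The
#' local modification scales the row's off-diagonal mass by the product of
#' the MAF, planted-region and chromosome-end multipliers (capped so the
#' error mass never exceeds 0.95), then restores the diagonal so the row
#' sums to 1. The effective row is also returned as the call's posterior
#' probability triple, so info scores computed from the posteriors are
#' consistent with the realized confusion frequencies. The missingness
#' pattern of the truth panel is preserved untouched. Markers monomorphic
#' in truth are copied error-free: wrong calls at fixed markers are the
#' province of [inject_spurious_segregation()], which controls their rate
#' and frequency scale separately.
#'
#' @param truth a `genotype_matrix`.
#' @param model an [error_model()].
#' @param seed integer seed.
#' @param chr_lengths optional named vector of chromosome lengths (bp) for
#'   the end gradient; defaults to the maximum marker position per
#'   chromosome.
#' @return List with `matrix` (the error-injected `genotype_matrix`) and
#'   `posteriors` (array n_samples x n_markers x 3, `NA` at missing calls).
#' @export
inject_errors <- function(truth, model, seed = 1L, chr_lengths = NULL) {
  stopifnot(inherits(model, "error_model"))
  set.seed(as.integer(seed))
  g <- truth$geno
  n <- nrow(g); m <- ncol(g)
  freq <- alt_freq(truth)
  freq[is.na(freq)] <- 0
  mult <- error_multipliers(truth$map, freq, model, chr_lengths)
  # truth-monomorphic markers are imputed error-free here: spurious
  # segregation at fixed markers has its own channel with its own rate
  # (inject_spurious_segregation), mirroring the near-perfect fixed-SNP
  # concordance seen in real panels
  mult[pmin(freq, 1 - freq) == 0] <- 0

  # per-marker effective rows: prob[m, true_g, emitted_g]
  base <- model$transition
  prob <- array(0, c(m, 3L, 3L))
  for (gt in 1:3) {
    off <- base[gt, -gt]
    off_mass <- sum(off) * mult
    cap <- pmin(1, 0.95 / pmax(off_mass, .Machine$double.eps))
    eff_mult <- mult * cap
    for (e in setdiff(1:3, gt)) prob[, gt, e] <- base[gt, e] * eff_mult
    prob[, gt, gt] <- 1 - (sum(off) * eff_mult)
  }

  jj <- rep(seq_len(m), each = n)
  gv <- as.integer(g) + 1L                     # column-major: n fast index
  ok <- !is.na(gv)
  emitted <- rep(NA_integer_, n * m)
  c1 <- prob[cbind(jj[ok], gv[ok], 1L)]
  c2 <- c1 + prob[cbind(jj[ok], gv[ok], 2L)]
  u <- stats::runif(sum(ok))
  emitted[ok] <- (u > c1) + (u > c2)
  imp <- matrix(emitted, n, m)

  post <- array(NA_real_, c(n, m, 3L))
  for (e in 1:3) {
    pe <- rep(NA_real_, n * m)
    pe[ok] <- prob[cbind(jj[ok], gv[ok], e)]
    post[, , e] <- matrix(pe, n, m)
  }
  list(matrix = genotype_matrix(imp, truth$samples, truth$map),
       posteriors = post)
}

#' Inject spurious segregation at truth-monomorphic markers
#'
#' Selects a Bernoulli fraction `rate` of the markers that are monomorphic
#' in the truth panel and replaces their imputed calls with low-frequency
#' wrong genotypes: for each affected marker a frequency is drawn from an
#' exponential distribution with mean `freq_scale` (capped at 0.5),
#' realized as `max(1, round(2N f))` minor-allele copies placed at
#' uniformly sampled allele slots, so every affected marker segregates and
#' the mean imputed MAF tracks `freq_scale`. Markers fixed for REF gain
#' ALT alleles and markers fixed for ALT gain REF alleles.
#'
#' @param imputed the imputed `genotype_matrix` to modify.
#' @param truth the truth `genotype_matrix` defining the monomorphic set.
#' @param rate fraction of monomorphic markers affected, in \[0, 1\].
#' @param freq_scale mean imputed MAF of affected markers.
#' @param seed integer seed.
#' @return The modified `genotype_matrix`.
#' @export
inject_spurious_segregation <- function(imputed, truth, rate, freq_scale,
                                        seed = 1L) {
  if (rate < 0 || rate > 1)
    stop("inject_spurious_segregation: rate must lie in [0, 1]")
  set.seed(as.integer(seed))
  p <- alt_freq(truth)
  mono <- which(!is.na(p) & (p == 0 | p == 1))
  if (length(mono) == 0L) return(imputed)
  hit <- mono[stats::runif(length(mono)) < rate]
  g <- imputed$geno
  n <- nrow(g)
  for (j in hit) {
    f <- min(stats::rexp(1L, rate = 1 / freq_scale), 0.5)
    k <- max(1L, round(2L * n * f))
    slots <- sample.int(2L * n, k)            # allele slots, 2 per sample
    d <- tabulate((slots + 1L) %/% 2L, nbins = n)
    if (p[j] == 1) d <- 2L - d                # fixed for ALT: minor = REF
    miss <- is.na(g[, j])
    g[, j] <- d
    g[miss, j] <- NA_integer_
  }
  genotype_matrix(g, imputed$samples, imputed$map)
}

#' Naive nearest-haplotype reference imputer
#'
#' A deliberately simple stand-in for haplotype-based imputation software,
#' used to study reference-panel composition effects. Reference markers are
#' processed in windows of `window` markers per chromosome; within each
#' window every target sample's diplotype is approximated greedily by the
#' two reference haplotypes minimizing dosage mismatch on the markers
#' observed in the target, and unobserved markers are copied from the
#' chosen pair. Ties resolve to the first (lowest-index) haplotype, so
#' haplotype order in the reference is meaningful for reproducibility.
#'
#' @param target a low-density `genotype_matrix`; its markers must be a
#'   subset of the reference markers.
#' @param reference a `haplotype_set` at full density.
#' @param window reference-marker count per matching window (default 200).
#' @return A `genotype_matrix` on the full reference marker map.
#' @export
naive_reference_imputer <- function(target, reference, window = 200L) {
  rkey <- marker_key(reference$map)
  tkey <- marker_key(target$map)
  if (!all(tkey %in% rkey))
    stop("naive_reference_imputer: target markers not a subset of reference")
  m <- nrow(reference$map)
  n <- n_samples(target)
  obs_col <- match(rkey, tkey)                 # NA where unobserved
  out <- matrix(0L, n, m)
  chr_idx <- split(seq_len(m), factor(reference$map$chr,
                                      unique(reference$map$chr)))
  H <- reference$haps
  for (idx in chr_idx) {
    starts <- seq(1L, length(idx), by = window)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      tcols <- obs_col[win]
      obs <- win[!is.na(tcols)]
      if (length(obs) < 2L)
        stop("naive_reference_imputer: window with fewer than 2 observed ",
             "markers; increase `window`")
      Hw <- H[, obs, drop = FALSE]
      G <- target$geno[, obs_col[obs], drop = FALSE]
      for (i in seq_len(n)) {
        gi <- G[i, ]
        use <- !is.na(gi)
        if (sum(use) < 2L)
          stop("naive_reference_imputer: sample ", target$samples[i],
               " has fewer than 2 observed markers in a window")
        gu <- gi[use]
        Hu <- Hw[, use, drop = FALSE]
        # greedy: h1 penalised where it is incompatible with the genotype
        c1 <- Hu %*% (gu == 0) + (1 - Hu) %*% (gu == 2)
        h1 <- which.min(c1)
        c2 <- abs(sweep(Hu, 2L, gu - Hu[h1, ])) %*% rep(1, sum(use))
        h2 <- which.min(c2)
        out[i, win] <- H[h1, win] + H[h2, win]
      }
    }
  }
  genotype_matrix(out, target$samples, reference$map)
}

#' Simulate a complete truth/masked/imputed panel triple
#'
#' Convenience wrapper running the full generator: founder haplotypes,
#' mosaic descendants (the truth panel), a low-density mask, error
#' injection and spurious segregation at fixed markers. All randomness
#' derives from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with `truth`, `masked`, `imputed` (`genotype_matrix`),
#'   `posteriors` (array), `founders` (`haplotype_set`) and `config`.
#' @export
simulate_panel_set <- function(config = simulation_config()) {
  founders <- simulate_founder_haplotypes(config)
  desc <- simulate_descendants(founders, config$n_samples,
                               config$switch_rate,
                               seed = config$seed + 1L,
                               missing_rate = config$missing_rate)
  truth <- desc$matrix
  masked <- mask_to_density(truth, config$mask_keep_fraction,
                            seed = config$seed + 2L)
  inj <- inject_errors(truth, config$error_model, seed = config$seed + 3L,
                       chr_lengths = stats::setNames(
                         config$chr_length_bp,
                         as.character(seq_len(config$n_chr))))
  imputed <- inject_spurious_segregation(inj$matrix, truth,
                                         config$spurious_rate,
                                         config$spurious_freq_scale,
                                         seed = config$seed + 4L)
  list(truth = truth, masked = masked, imputed = imputed,
       posteriors = inj$posteriors, founders = founders, config = config)
}
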