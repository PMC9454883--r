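compared_mask <- function(pair) !is.na(pair$truth$geno) & !is.na(pair$imputed$geno)

freq_over <- function(geno, mask) {
  s <- colSums(ifelse(mask, geno, 0), na.rm = TRUE)
  n <- colSums(mask)
  out <- s / (2 * n)
  out[n == 0L] <- NA_real_
  out
}

#' Concordance rate between imputed and true genotypes
#'
#' The concordance rate (CR) is the fraction of correctly imputed genotype
#' calls. Comparison is pairwise complete: calls missing in either panel
#' are excluded from the denominator. Returns the overall CR together with
#' per-sample and per-marker breakdowns and a summary (min/mean/max and the
#' fraction of markers with CR below 0.9). Samples or markers with zero
#' compared calls get `NA` and are excluded from summaries.
#'
#' @param pair a [panel_pair()].
#' @return List of class `concordance_result` with elements `overall`
#'   (fraction in \[0, 1\]), `per_sample`, `per_snp` (data.frames) and
#'   `summary`.
#' @export
concordance <- function(pair) {
  stopifnot(inherits(pair, "panel_pair"))
  tm <- pair$truth$geno; im <- pair$imputed$geno
  cmp <- compared_mask(pair)
  eq <- tm == im & cmp
  eq[is.na(eq)] <- FALSE
  n_cmp <- sum(cmp)
  if (n_cmp == 0L) stop("concordance: no pairwise non-missing calls")
  overall <- sum(eq) / n_cmp

  s_n <- rowSums(cmp); s_cr <- rowSums(eq) / s_n
  s_cr[s_n == 0L] <- NA_real_
  m_n <- colSums(cmp); m_cr <- colSums(eq) / m_n
  m_cr[m_n == 0L] <- NA_real_

  p_t <- freq_over(tm, cmp)
  p_i <- freq_over(im, cmp)
  per_sample <- data.frame(sample = pair$truth$samples, cr = s_cr,
                           n_compared = s_n, stringsAsFactors = FALSE)
  per_snp <- data.frame(chr = pair$truth$map$chr, pos = pair$truth$map$pos,
                        id = pair$truth$map$id, cr = m_cr, n_compared = m_n,
                        alt_freq_truth = p_t, alt_freq_imputed = p_i,
                        maf_truth = pmin(p_t, 1 - p_t),
                        stringsAsFactors = FALSE)
  def <- !is.na(m_cr)
  summ <- list(
    overall = overall,
    sample_cr = c(min = min(s_cr, na.rm = TRUE), mean = mean(s_cr, na.rm = TRUE),
                  max = max(s_cr, na.rm = TRUE)),
    snp_cr = c(min = min(m_cr, na.rm = TRUE), mean = mean(m_cr, na.rm = TRUE),
               max = max(m_cr, na.rm = TRUE)),
    frac_snps_below_0.9 = mean(m_cr[def] < 0.9))
  structure(list(overall = overall, per_sample = per_sample,
                 per_snp = per_snp, summary = summ),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("overall concordance: %.4f (%d samples, %d markers)\n",
              x$overall, nrow(x$per_sample), nrow(x$per_snp)))
  invisible(x)
}

pearson_or_na <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pearson correlation between imputed and true dosages
#'
#' Per-sample and per-marker Pearson correlations of ALT-dosage vectors,
#' over pairwise non-missing calls. A vector with zero variance in either
#' panel (e.g. a truth-monomorphic marker), or fewer than two compared
#' calls, yields an undefined (`NA`) correlation; undefined entries are
#' excluded from mean summaries and counted separately.
#'
#' @param pair a [panel_pair()].
#' @return List of class `correlation_result` with `per_sample`, `per_snp`
#'   data.frames (column `r`) and `summary` (means over defined entries and
#'   undefined counts, plus the fractions of markers with r below 0.9, 0.8
#'   and 0.7).
#' @export
dosage_correlation <- function(pair) {
  stopifnot(inherits(pair, "panel_pair"))
  tm <- pair$truth$geno; im <- pair$imputed$geno
  n <- nrow(tm); m <- ncol(tm)
  s_r <- vapply(seq_len(n), function(i) pearson_or_na(tm[i, ], im[i, ]),
                numeric(1))
  m_r <- vapply(seq_len(m), function(j) pearson_or_na(tm[, j], im[, j]),
                numeric(1))
  def <- !is.na(m_r)
  summ <- list(
    sample_r = c(min = suppressWarnings(min(s_r, na.rm = TRUE)),
                 mean = mean(s_r, na.rm = TRUE),
                 max = suppressWarnings(max(s_r, na.rm = TRUE))),
    snp_r_mean = mean(m_r[def]),
    n_snp_undefined = sum(!def),
    frac_snps_r_below = c(`0.9` = mean(m_r[def] < 0.9),
                          `0.8` = mean(m_r[def] < 0.8),
                          `0.7` = mean(m_r[def] < 0.7)))
  structure(list(
    per_sample = data.frame(sample = pair$truth$samples, r = s_r,
                            stringsAsFactors = FALSE),
    per_snp = data.frame(chr = pair$truth$map$chr, pos = pair$truth$map$pos,
                         id = pair$truth$map$id, r = m_r,
                         stringsAsFactors = FALSE),
    summary = summ), class = "correlation_result")
}

#' Genotype confusion table
#'
#' Cross-tabulates true against imputed genotype classes over pairwise
#' non-missing calls, in the conventional layout with rows indexed by the
#' true (reference) genotype and columns by the imputed genotype.
#' Percentages are normalized within rows, so each non-empty row sums to
#' 100. The heterozygote error rate, 100 minus the het-row diagonal, is the
#' single hardest-class summary.
#'
#' @param pair a [panel_pair()].
#' @return Object of class `confusion_table`: list with `counts` (3x3),
#'   `row_pct` (3x3, `NA` rows where a true class is absent),
#'   `het_error_pct` and `n` (total compared calls).
#' @export
genotype_confusion <- function(pair) {
  stopifnot(inherits(pair, "panel_pair"))
  cmp <- compared_mask(pair)
  tv <- factor(pair$truth$geno[cmp], levels = 0:2)
  iv <- factor(pair$imputed$geno[cmp], levels = 0:2)
  counts <- unclass(table(true = tv, imputed = iv))
  lab <- c("homREF", "het", "homALT")
  dimnames(counts) <- list(true = lab, imputed = lab)
  rs <- rowSums(counts)
  row_pct <- 100 * counts / rs
  row_pct[rs == 0L, ] <- NA_real_
  het_error <- if (rs[2L] > 0L) 100 - row_pct[2L, 2L] else NA_real_
  structure(list(counts = counts, row_pct = row_pct,
                 het_error_pct = het_error, n = sum(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, digits = 2, ...) {
  cat("genotype confusion (row %):\n")
  print(round(x$row_pct, digits))
  cat(sprintf("heterozygote error rate: %.2f%% (n = %d calls)\n",
              x$het_error_pct, x$n))
  invisible(x)
}

#' Concordance by allele-frequency bin
#'
#' Averages per-marker concordance within frequency bins of width
#' `bin_width` (default 0.01). Markers are assigned by truth ALT frequency
#' to bins `[k w, (k+1) w)` with the final bin closed at 1; optionally the
#' folded minor-allele frequency is used instead (bins then cover
#' \[0, 0.5\]). Empty bins are flagged with `NA` means, never zero-filled.
#'
#' @param per_snp the `per_snp` data.frame from [concordance()].
#' @param bin_width bin width on the frequency axis.
#' @param by `"alt"` (default) to bin on ALT frequency, `"maf"` to bin on
#'   minor allele frequency.
#' @return data.frame with `bin_low`, `bin_high`, `n_markers`, `mean_cr`.
#' @export
af_binned_concordance <- function(per_snp, bin_width = 0.01,
                                  by = c("alt", "maf")) {
  by <- match.arg(by)
  f <- if (by == "alt") per_snp$alt_freq_truth else per_snp$maf_truth
  top <- if (by == "alt") 1 else 0.5
  nb <- ceiling(top / bin_width)
  ok <- !is.na(f) & !is.na(per_snp$cr)
  bin <- pmin(floor(f[ok] / bin_width), nb - 1L) + 1L   # closed last bin
  mean_cr <- tapply(per_snp$cr[ok], factor(bin, seq_len(nb)), mean)
  n <- tapply(per_snp$cr[ok], factor(bin, seq_len(nb)), length)
  n[is.na(n)] <- 0L
  data.frame(bin_low = (seq_len(nb) - 1L) * bin_width,
             bin_high = pmin(seq_len(nb) * bin_width, top),
             n_markers = as.integer(n),
             mean_cr = as.numeric(mean_cr))
}

#' Correlation between true and imputed allele frequencies
#'
#' Pearson correlation between the per-marker truth and imputed ALT-allele
#' frequencies (computed over each panel's non-missing calls at compared
#' markers). Monomorphic markers contribute as ordinary points. `NA` when
#' either frequency vector has zero variance.
#'
#' @param pair a [panel_pair()].
#' @return Scalar correlation, or `NA` if undefined.
#' @export
allele_frequency_correlation <- function(pair) {
  stopifnot(inherits(pair, "panel_pair"))
  p_t <- alt_freq(pair$truth)
  p_i <- alt_freq(pair$imputed)
  if (sum(!is.na(p_t) & !is.na(p_i)) < 2L)
    stop("allele_frequency_correlation: fewer than 2 markers with defined frequencies")
  pearson_or_na(p_t, p_i)
}

#' Fixed-marker (spurious segregation) report
#'
#' Profiles the markers monomorphic in the truth panel (truth MAF exactly
#' 0): how many there are, what fraction of them segregate spuriously in
#' the imputed panel (imputed MAF > 0), the mean imputed MAF among those,
#' and the concordance rate restricted to the monomorphic set.
#'
#' @param pair a [panel_pair()].
#' @return List of class `fixed_snp_report`: `n_total`, `n_monomorphic`,
#'   `monomorphic_pct`, `n_spurious`, `spurious_fraction`,
#'   `mean_spurious_maf`, `concordance_monomorphic`.
#' @export
fixed_snp_report <- function(pair) {
  stopifnot(inherits(pair, "panel_pair"))
  p_t <- alt_freq(pair$truth)
  maf_t <- pmin(p_t, 1 - p_t)
  mono <- which(!is.na(maf_t) & maf_t == 0)
  m <- n_markers(pair$truth)
  if (length(mono) == 0L) {
    return(structure(list(n_total = m, n_monomorphic = 0L,
                          monomorphic_pct = 0, n_spurious = 0L,
                          spurious_fraction = 0, mean_spurious_maf = NA_real_,
                          concordance_monomorphic = NA_real_),
                     class = "fixed_snp_report"))
  }
  sub_t <- subset_markers(pair$truth, mono)
  sub_i <- subset_markers(pair$imputed, mono)
  maf_i <- marker_maf(sub_i)
  spur <- which(!is.na(maf_i) & maf_i > 0)
  cmp <- !is.na(sub_t$geno) & !is.na(sub_i$geno)
  eq <- sub_t$geno == sub_i$geno & cmp
  eq[is.na(eq)] <- FALSE
  structure(list(
    n_total = m,
    n_monomorphic = length(mono),
    monomorphic_pct = 100 * length(mono) / m,
    n_spurious = length(spur),
    spurious_fraction = length(spur) / length(mono),
    mean_spurious_maf = if (length(spur)) mean(maf_i[spur]) else NA_real_,
    concordance_monomorphic = sum(eq) / sum(cmp)),
    class = "fixed_snp_report")
}

#' Discordance between two genotype panels
#'
#' Overall discordance (1 - concordance over pairwise non-missing calls)
#' between two harmonized, intersected panels, with two optional strata:
#' the calls that were missing in panel `a` before gap-filling (to separate
#' phasing-stage from imputation-stage error) and an arbitrary marker
#' subset (e.g. excluding the original low-density panel's markers).
#' Discordance and concordance sum to 1 on every stratum.
#'
#' @param a,b `genotype_matrix` objects with identical samples and maps.
#' @param premissing optional logical matrix (same dimensions) marking
#'   calls originally missing in `a`.
#' @param marker_subset optional logical or integer vector of markers to
#'   restrict an additional stratified rate to.
#' @return List with `overall`, `premissing` and `subset` discordance
#'   fractions (the latter two `NA` when not requested) and `n_compared`.
#' @export
panel_discordance <- function(a, b, premissing = NULL, marker_subset = NULL) {
  pair <- panel_pair(a, b)
  cmp <- compared_mask(pair)
  neq <- a$geno != b$geno & cmp
  neq[is.na(neq)] <- FALSE
  if (sum(cmp) == 0L) stop("panel_discordance: no compared calls")
  rate <- function(mask) {
    nc <- sum(cmp & mask)
    if (nc == 0L) NA_real_ else sum(neq & mask) / nc
  }
  pre <- NA_real_
  if (!is.null(premissing)) {
    stopifnot(identical(dim(premissing), dim(a$geno)))
    pre <- rate(premissing)
  }
  sub <- NA_real_
  if (!is.null(marker_subset)) {
    msk <- matrix(FALSE, nrow(a$geno), ncol(a$geno))
    msk[, marker_subset] <- TRUE
    sub <- rate(msk)
  }
  list(overall = sum(neq) / sum(cmp), premissing = pre, subset = sub,
       n_compared = sum(cmp))
}

#' IMPUTE-style info score
#'
#' Ratio of observed to expected statistical information about the allele
#' frequency, computed from per-sample genotype posterior probability
#' triples: with expected dosage e = P(het) + 2 P(homALT) and second moment
#' f = P(het) + 4 P(homALT), and estimated frequency theta = sum(e) / (2N),
#' the score is 1 - sum(f - e^2) / (2N theta (1 - theta)). It is defined as
#' 1 when theta is 0 or 1 and clamped to \[0, 1\].
#'
#' @param posteriors for a single marker, an N x 3 matrix of posterior
#'   probabilities (columns = genotype 0/1/2); rows must sum to 1. Rows
#'   with any `NA` (missing calls) are dropped.
#' @param tol tolerance on the row-sum check.
#' @return Scalar info score in \[0, 1\].
#' @export
impute_info_score <- function(posteriors, tol = 1e-6) {
  p <- as.matrix(posteriors)
  if (ncol(p) != 3L) stop("impute_info_score: posteriors must have 3 columns")
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) == 0L) return(NA_real_)
  if (any(abs(rowSums(p) - 1) > tol))
    stop("impute_info_score: posterior triples must sum to 1")
  e <- p[, 2L] + 2 * p[, 3L]
  f <- p[, 2L] + 4 * p[, 3L]
  N <- nrow(p)
  theta <- sum(e) / (2 * N)
  if (theta <= 0 || theta >= 1) return(1)
  info <- 1 - sum(f - e^2) / (2 * N * theta * (1 - theta))
  min(max(info, 0), 1)
}

#' Info scores for every marker of a posterior tensor
#'
#' @param posteriors array n_samples x n_markers x 3, as produced by
#'   [inject_errors()].
#' @return Numeric vector of per-marker info scores.
#' @export
marker_info_scores <- function(posteriors) {
  stopifnot(length(dim(posteriors)) == 3L, dim(posteriors)[3L] == 3L)
  vapply(seq_len(dim(posteriors)[2L]),
         function(j) impute_info_score(posteriors[, j, ]), numeric(1))
}

#' Evaluate an info-score filter against realized concordance
#'
#' Quantifies how well the info score predicts imputation quality: its
#' correlation with per-marker concordance and with allele frequency, and
#' the effect of retaining only markers with info >= `cutoff` (mean CR of
#' retained and removed sets, fraction of genotype calls retained, and the
#' fraction of markers with CR < 0.9 before and after filtering).
#'
#' @param info per-marker info scores, aligned with `per_snp`.
#' @param per_snp the `per_snp` data.frame from [concordance()].
#' @param cutoff retention threshold in \[0, 1\].
#' @param strict retain with `info > cutoff` instead of `>=`.
#' @return List of class `info_score_report`.
#' @export
info_filter_evaluation <- function(info, per_snp, cutoff = 0.6,
                                   strict = FALSE) {
  if (cutoff < 0 || cutoff > 1)
    stop("info_filter_evaluation: cutoff must lie in [0, 1]")
  stopifnot(length(info) == nrow(per_snp))
  keep <- if (strict) info > cutoff else info >= cutoff
  def <- !is.na(per_snp$cr) & !is.na(info)
  cr <- per_snp$cr
  structure(list(
    cutoff = cutoff,
    cor_info_cr = pearson_or_na(info, cr),
    cor_info_freq = pearson_or_na(info, per_snp$alt_freq_truth),
    n_retained = sum(keep, na.rm = TRUE),
    mean_cr_retained = mean(cr[def & keep]),
    mean_cr_removed = if (any(def & !keep)) mean(cr[def & !keep]) else NA_real_,
    frac_calls_retained = sum(per_snp$n_compared[keep], na.rm = TRUE) /
      sum(per_snp$n_compared),
    frac_cr_below_0.9_before = mean(cr[def] < 0.9),
    frac_cr_below_0.9_after = if (any(def & keep))
      mean(cr[def & keep] < 0.9) else NA_real_),
    class = "info_score_report")
}
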