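test_that("concordance counts matches over pairwise non-missing calls", {
  truth <- mk_gm(matrix(c(0L, 1L, 2L, 1L, 0L), 1, 5))
  imp <- mk_gm(matrix(c(0L, 1L, 1L, 1L, 0L), 1, 5))
  cc <- concordance(panel_pair(truth, imp))
  expect_equal(cc$per_sample$cr, 0.8)            # 4 of 5 calls agree
  expect_equal(cc$overall, 0.8)
  # a missing imputed call shrinks the denominator, it is not an error
  imp2 <- mk_gm(matrix(c(0L, 1L, NA, 1L, 0L), 1, 5))
  cc2 <- concordance(panel_pair(truth, imp2))
  expect_equal(cc2$per_sample$n_compared, 4L)
  expect_equal(cc2$per_sample$cr, 1)
  # identical panels are perfectly concordant everywhere
  id <- concordance(panel_pair(truth, truth))
  expect_equal(id$overall, 1)
  expect_true(all(id$per_snp$cr == 1))
})

test_that("dosage correlations match the direct Pearson formula", {
  truth <- mk_gm(matrix(c(0L, 1L, 2L, 0L, 1L), 1, 5))
  imp <- mk_gm(matrix(c(0L, 2L, 2L, 0L, 0L), 1, 5))
  r <- dosage_correlation(panel_pair(truth, imp))$per_sample$r
  expect_equal(r, pearson_oracle(c(0, 1, 2, 0, 1), c(0, 2, 2, 0, 0)))
  # random panels: per-sample and per-marker r against the raw-sum oracle
  pair <- rand_pair(n = 12, m = 30, err = 0.3, miss = 0.1, seed = 7)
  res <- dosage_correlation(pair)
  for (i in c(1, 5, 12))
    expect_equal(res$per_sample$r[i],
                 pearson_oracle(pair$truth$geno[i, ], pair$imputed$geno[i, ]))
  for (j in c(2, 17, 30))
    expect_equal(res$per_snp$r[j],
                 pearson_oracle(pair$truth$geno[, j], pair$imputed$geno[, j]))
})

test_that("zero-variance vectors give undefined correlations excluded from means", {
  truth <- mk_gm(rbind(c(0L, 0L, 1L), c(0L, 1L, 2L), c(0L, 2L, 0L)))
  imp <- mk_gm(rbind(c(0L, 0L, 1L), c(1L, 1L, 2L), c(0L, 2L, 0L)))
  res <- dosage_correlation(panel_pair(truth, imp))
  expect_true(is.na(res$per_snp$r[1]))           # truth-monomorphic marker
  expect_equal(res$summary$n_snp_undefined, 1L)
  expect_equal(res$summary$snp_r_mean,
               mean(res$per_snp$r[2:3]))
})

test_that("confusion rows are percentages of true-genotype classes", {
  # 10 true hets: 9 imputed het, 1 imputed hom-ALT
  truth <- mk_gm(matrix(rep(1L, 10), 1), mk_map(10))
  imp <- mk_gm(matrix(c(rep(1L, 9), 2L), 1), mk_map(10))
  ct <- genotype_confusion(panel_pair(truth, imp))
  expect_equal(unname(ct$row_pct["het", ]), c(0, 90, 10))
  expect_equal(ct$het_error_pct, 10)
  expect_true(all(is.na(ct$row_pct["homREF", ])))  # empty true class
  # trace identity and row sums on random panels
  for (seed in 1:3) {
    pair <- rand_pair(n = 15, m = 40, err = 0.2, miss = 0.05, seed = seed)
    ct <- genotype_confusion(pair)
    cc <- concordance(pair)
    expect_equal(sum(diag(ct$counts)) / sum(ct$counts), cc$overall)
    rs <- rowSums(ct$row_pct)
    expect_true(all(abs(rs[!is.na(rs)] - 100) < 0.01))
  }
})

test_that("frequency bins assign markers with a closed final bin", {
  per_snp <- data.frame(cr = c(1.0, 0.8, 0.5, 0.6),
                        alt_freq_truth = c(0.005, 0.015, 1.0, 0.5),
                        maf_truth = c(0.005, 0.015, 0, 0.5),
                        n_compared = 10L)
  b <- af_binned_concordance(per_snp, 0.01)
  expect_equal(nrow(b), 100L)
  expect_equal(b$mean_cr[1], 1.0)
  expect_equal(b$mean_cr[2], 0.8)
  expect_equal(b$mean_cr[100], 0.5)   # frequency 1.0 lands in the last bin
  expect_equal(b$n_markers[51], 1L)   # 0.5 in [0.50, 0.51)
  expect_true(all(is.na(b$mean_cr[b$n_markers == 0])))
  # single populated bin reproduces the plain mean
  one <- data.frame(cr = c(0.9, 0.7), alt_freq_truth = 0.5,
                    maf_truth = 0.5, n_compared = 10L)
  b1 <- af_binned_concordance(one, 0.01)
  expect_equal(b1$mean_cr[51], 0.8)
  expect_equal(sum(b1$n_markers), 2L)
})

test_that("allele-frequency correlation follows the Pearson oracle", {
  pair <- rand_pair(n = 30, m = 3, err = 0.5, seed = 2)
  expect_equal(allele_frequency_correlation(pair),
               pearson_oracle(alt_freq(pair$truth), alt_freq(pair$imputed)))
  id <- rand_pair(n = 10, m = 20, err = 0, seed = 3)
  expect_equal(allele_frequency_correlation(id), 1)
  # monomorphic markers participate as ordinary points
  truth <- mk_gm(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L)))
  imp <- mk_gm(rbind(c(0L, 2L, 0L), c(0L, 2L, 1L)))
  expect_equal(allele_frequency_correlation(panel_pair(truth, imp)),
               pearson_oracle(c(0, 1, 0.5), c(0, 1, 0.25)))
})

test_that("fixed-marker report counts spurious segregation by hand", {
  # 10 truth-fixed markers, 3 segregate after imputation
  truth <- mk_gm(matrix(0L, 4, 10))
  imp_g <- matrix(0L, 4, 10)
  imp_g[1, 1] <- 1L; imp_g[2, 5] <- 1L; imp_g[c(1, 3), 9] <- 2L
  fx <- fixed_snp_report(panel_pair(truth, mk_gm(imp_g)))
  expect_equal(fx$n_monomorphic, 10L)
  expect_equal(fx$monomorphic_pct, 100)
  expect_equal(fx$spurious_fraction, 0.3)
  expect_equal(fx$mean_spurious_maf, mean(c(1 / 8, 1 / 8, 4 / 8)))
  expect_equal(fx$concordance_monomorphic, 1 - 4 / 40)
  # clean imputation: nothing spurious, concordance 100%
  clean <- fixed_snp_report(panel_pair(truth, truth))
  expect_equal(clean$spurious_fraction, 0)
  expect_equal(clean$concordance_monomorphic, 1)
})

test_that("panel discordance complements concordance on every stratum", {
  g <- matrix(sample(0:2, 200, replace = TRUE), 2, 100)
  a <- mk_gm(g, mk_map(100))
  b_g <- g; b_g[1, 1] <- (g[1, 1] + 1L) %% 3L    # exactly one mismatch
  b <- mk_gm(b_g, mk_map(100))
  d <- panel_discordance(a, b)
  expect_equal(d$overall, 1 / 200)               # 0.5%
  expect_equal(panel_discordance(a, a)$overall, 0)
  # premissing stratum and complement identity
  pre <- matrix(FALSE, 2, 100); pre[1, 1:10] <- TRUE
  d2 <- panel_discordance(a, b, premissing = pre, marker_subset = 1:10)
  expect_equal(d2$premissing, 1 / 10)
  expect_equal(d2$subset, 1 / 20)
  cc <- concordance(panel_pair(a, b))
  expect_equal(d$overall + cc$overall, 1)
})

test_that("info scores evaluate the observed/expected information ratio", {
  # certainty: all mass on one genotype per sample
  certain <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(impute_info_score(certain), 1)
  # theta = 0 convention
  expect_equal(impute_info_score(rbind(c(1, 0, 0), c(1, 0, 0))), 1)
  # two samples at (0.25, 0.5, 0.25): independent evaluation of the formula
  p <- rbind(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))
  e <- p[, 2] + 2 * p[, 3]; f <- p[, 2] + 4 * p[, 3]
  theta <- sum(e) / 4
  oracle <- 1 - sum(f - e^2) / (4 * theta * (1 - theta))
  expect_equal(impute_info_score(p), max(0, oracle))
  expect_equal(impute_info_score(p), 0)  # maximum posterior uncertainty
  expect_error(impute_info_score(rbind(c(0.5, 0.1, 0.1))), "sum to 1")
})

test_that("info-score filtering splits markers by hand-computed means", {
  info <- c(0.95, 0.85, 0.75, 0.65, 0.61, 0.55, 0.45, 0.35, 0.25, 0.15)
  cr <- c(0.99, 0.98, 0.97, 0.96, 0.80, 0.94, 0.93, 0.85, 0.91, 0.90)
  per_snp <- data.frame(cr = cr, alt_freq_truth = seq(0.05, 0.5, 0.05),
                        n_compared = rep(100L, 10))
  rep6 <- info_filter_evaluation(info, per_snp, cutoff = 0.6)
  expect_equal(rep6$n_retained, 5L)
  expect_equal(rep6$mean_cr_retained, mean(cr[1:5]))
  expect_equal(rep6$mean_cr_removed, mean(cr[6:10]))
  expect_equal(rep6$frac_calls_retained, 0.5)
  expect_equal(rep6$frac_cr_below_0.9_before, mean(cr < 0.9))
  expect_equal(rep6$frac_cr_below_0.9_after, mean(cr[1:5] < 0.9))
  expect_equal(rep6$cor_info_cr, pearson_oracle(info, cr))
  # cutoff 0 retains everything; the removed-set mean is undefined
  rep0 <- info_filter_evaluation(info, per_snp, cutoff = 0)
  expect_equal(rep0$n_retained, 10L)
  expect_true(is.na(rep0$mean_cr_removed))
  expect_error(info_filter_evaluation(info, per_snp, cutoff = 2), "cutoff")
})

test_that("relabelling REF/ALT in both panels leaves accuracies invariant", {
  pair <- rand_pair(n = 10, m = 25, err = 0.25, miss = 0.05, seed = 9)
  flip_mk <- sample(25, 10)
  flip <- function(gm) {
    g <- gm$geno
    g[, flip_mk] <- 2L - g[, flip_mk, drop = FALSE]
    map <- gm$map
    tmp <- map$ref[flip_mk]
    map$ref[flip_mk] <- map$alt[flip_mk]; map$alt[flip_mk] <- tmp
    genotype_matrix(g, gm$samples, marker_map(map$chr, map$pos, map$id,
                                              map$ref, map$alt))
  }
  flipped <- panel_pair(flip(pair$truth), flip(pair$imputed))
  expect_equal(concordance(flipped)$overall, concordance(pair)$overall)
  expect_equal(concordance(flipped)$per_snp$cr, concordance(pair)$per_snp$cr)
  r0 <- dosage_correlation(pair)$per_snp$r
  r1 <- dosage_correlation(flipped)$per_snp$r
  expect_equal(abs(r1), abs(r0))
  # confusion: flipped markers swap homREF/homALT, so totals per class move
  # but the trace (and hence overall CR) is unchanged
  expect_equal(sum(diag(genotype_confusion(flipped)$counts)),
               sum(diag(genotype_confusion(pair)$counts)))
})

test_that("a perfect imputation scores 1 on every defined metric", {
  cfg <- simulation_config(n_chr = 1, markers_per_chr = 300, n_samples = 25,
                           error_model = identity_error_model(),
                           spurious_rate = 0, seed = 21)
  sim <- simulate_panel_set(cfg)
  pair <- panel_pair(sim$truth, sim$imputed)
  expect_equal(concordance(pair)$overall, 1)
  r <- dosage_correlation(pair)$per_snp$r
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-12))
  expect_equal(allele_frequency_correlation(pair), 1)
})
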