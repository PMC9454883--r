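# brute-force windowed median: the independent oracle for the running median
brute_runmed <- function(v, w) {
  h <- (w - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i)
    stats::median(v[max(1, i - h):min(n, i + h)]), numeric(1))
}

# brute-force gap grouping: the independent oracle for region merging
brute_merge <- function(chr, pos, max_gap, min_snps) {
  out <- NULL
  for (ch in unique(chr)) {
    p <- pos[chr == ch]
    cur <- p[1]
    members <- p[1]
    for (x in p[-1]) {
      if (x - members[length(members)] > max_gap) {
        if (length(members) >= min_snps)
          out <- rbind(out, data.frame(chr = ch, start = members[1],
                                       end = members[length(members)],
                                       length = members[length(members)] - members[1],
                                       n_snps = length(members)))
        members <- x
      } else members <- c(members, x)
    }
    if (length(members) >= min_snps)
      out <- rbind(out, data.frame(chr = ch, start = members[1],
                                   end = members[length(members)],
                                   length = members[length(members)] - members[1],
                                   n_snps = length(members)))
  }
  out
}

test_that("the running median shrinks its window at chromosome edges", {
  tr <- accuracy_track("1", c(10, 20, 30, 40, 50), c(1, 2, 3, 4, 5) / 5)
  sm <- running_median_track(tr, 3)
  expect_equal(sm$value, c(1.5, 2, 3, 4, 4.5) / 5)
  # constants and the degenerate window are identities
  const <- accuracy_track("1", 1:20 * 10, rep(0.7, 20))
  expect_equal(running_median_track(const, 5)$value, rep(0.7, 20))
  expect_equal(running_median_track(tr, 1)$value, tr$value)
  expect_error(running_median_track(tr, 4), "odd")
})

test_that("running median matches the brute-force oracle on random tracks", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(3:400, 1)
    w <- sample(c(3, 5, 21, 101), 1)
    v <- round(runif(n), 3)
    tr <- accuracy_track("1", seq_len(n) * 50, v)
    expect_equal(running_median_track(tr, w)$value, brute_runmed(v, w))
  }
  # smoothing respects chromosome boundaries
  v2 <- round(runif(60), 3)
  two <- accuracy_track(rep(c("1", "2"), each = 30),
                        rep(seq_len(30) * 10, 2), v2)
  sm <- running_median_track(two, 7)
  expect_equal(sm$value[1:30], brute_runmed(v2[1:30], 7))
  expect_equal(sm$value[31:60], brute_runmed(v2[31:60], 7))
})

test_that("flagging uses the nearest-rank genome-wide quantile", {
  set.seed(4)
  v <- sample(seq(0.3, 0.999, length.out = 1000))     # 1000 distinct values
  tr <- accuracy_track("1", seq_len(1000) * 100, v)
  fl <- flag_low_snps(tr, 0.1)
  expect_equal(fl$n_flagged, 1L)                       # ceiling(0.001*1000) = 1
  expect_equal(fl$cutoff, min(v))
  # ties at the cutoff are all flagged (<= rule)
  const <- accuracy_track("1", 1:50 * 10, rep(0.5, 50))
  expect_equal(flag_low_snps(const, 0.1)$n_flagged, 50L)
  expect_equal(flag_low_snps(tr, 100)$n_flagged, 1000L)
  expect_error(flag_low_snps(tr, 0), "percentile")
})

test_that("region merging follows the gap and minimum-size rules", {
  # two clusters far apart on one chromosome become two regions
  flagged <- data.frame(chr = "4",
                        pos = c(105573863, 105580000, 105589511,
                                112830880, 113000000, 113341416))
  reg <- merge_regions(flagged, scan_parameters())
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(105573863, 112830880))
  expect_equal(reg$end, c(105589511, 113341416))
  expect_equal(reg$length, reg$end - reg$start)
  # a gap of exactly 1 Mb still joins (the split needs strictly more)
  exact <- data.frame(chr = "1", pos = c(1e6, 2e6))
  expect_equal(nrow(merge_regions(exact, scan_parameters())), 1L)
  just_over <- data.frame(chr = "1", pos = c(1e6, 2e6 + 1))
  expect_equal(nrow(merge_regions(just_over, scan_parameters())), 0L)  # singletons dropped
  # singleton regions are discarded under min_snps = 2
  lone <- data.frame(chr = "2", pos = c(100, 5e6))
  expect_equal(nrow(merge_regions(lone, scan_parameters())), 0L)
})

test_that("region merging matches a brute-force grouping oracle", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(2:80, 1)
    pos <- sort(sample.int(3e7, n))
    chr <- sort(sample(c("1", "2"), n, TRUE))
    pos <- ave(pos, chr, FUN = sort)
    gap <- sample(c(5e5, 1e6, 2e6), 1)
    params <- scan_parameters(max_gap_bp = gap, min_snps = sample(1:3, 1))
    got <- merge_regions(data.frame(chr = chr, pos = pos), params)
    want <- brute_merge(chr, pos, gap, params$min_snps)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("per-chromosome counts aggregate the published benchmark regions", {
  reg <- benchmark_regions()
  counts <- per_chromosome_flag_counts(reg)
  expect_equal(counts$n_snps[counts$chr == "4"], 15339L)
  expect_equal(counts$n_snps[counts$chr == "17"], 9177L)
  expect_equal(counts$n_snps[counts$chr == "10"], 5326L)
  expect_equal(counts$chr[1], "4")          # ranked by flagged-SNP count
  empty <- merge_regions(data.frame(chr = character(0), pos = numeric(0)),
                         scan_parameters())
  expect_equal(nrow(per_chromosome_flag_counts(empty)), 0L)
})

test_that("end-distance profile uses the nearest chromosome end", {
  tr <- accuracy_track("1", c(5, 50, 98), c(0.2, 0.9, 0.4))
  prof <- end_distance_profile(tr, c("1" = 100), bin_width_bp = 10)
  expect_equal(prof$dist_low, c(0, 50))     # distances 5, 2 -> bin 0; 50 -> bin 5
  expect_equal(prof$mean_value, c(mean(c(0.2, 0.4)), 0.9))
  flat <- accuracy_track("1", seq(10, 90, 10), rep(0.5, 9))
  pf <- end_distance_profile(flat, c("1" = 100), 10)
  expect_true(all(pf$mean_value == 0.5))
  expect_error(end_distance_profile(tr, c("1" = 90), 10),
               "exceeds stated chromosome length")
})

test_that("a chromosome-end error gradient shows up in the first distance bin", {
  lower <- 0
  for (seed in 1:3) {
    em <- error_model(end_gradient = list(strength = 4, scale_bp = 5e6))
    cfg <- simulation_config(n_chr = 2, markers_per_chr = 600, n_samples = 50,
                             af_shape1 = 2, af_shape2 = 2,
                             monomorphic_fraction = 0, error_model = em,
                             spurious_rate = 0, seed = seed)
    sim <- simulate_panel_set(cfg)
    cc <- concordance(panel_pair(sim$truth, sim$imputed))
    tr <- accuracy_track(cc$per_snp$chr, cc$per_snp$pos, cc$per_snp$cr)
    prof <- end_distance_profile(tr, c("1" = 1e8, "2" = 1e8), 2e6)
    lower <- lower + (prof$mean_value[1] < mean(tr$value))
  }
  expect_equal(lower, 3)
})

test_that("the full scan recovers a planted low-accuracy region", {
  for (seed in 1:3) {
    reg <- data.frame(chr = "1", start = 4.0e7, end = 5.5e7, multiplier = 40)
    em <- error_model(transition = matrix(c(0.995, 0.004, 0.001,
                                            0.005, 0.99, 0.005,
                                            0.001, 0.004, 0.995), 3,
                                          byrow = TRUE),
                      bad_regions = reg)
    cfg <- simulation_config(n_chr = 1, markers_per_chr = 2000,
                             n_samples = 60, af_shape1 = 2, af_shape2 = 2,
                             monomorphic_fraction = 0, error_model = em,
                             spurious_rate = 0, seed = seed + 100)
    sim <- simulate_panel_set(cfg)
    cc <- concordance(panel_pair(sim$truth, sim$imputed))
    tr <- accuracy_track(cc$per_snp$chr, cc$per_snp$pos, cc$per_snp$cr)
    window <- 101L
    planted_idx <- which(tr$pos >= reg$start & tr$pos <= reg$end)
    pct <- 100 * length(planted_idx) / nrow(tr)
    res <- scan_regions(tr, scan_parameters(window = window,
                                            percentile = pct))
    hit <- res$regions[res$regions$end >= reg$start &
                         res$regions$start <= reg$end, ]
    expect_equal(nrow(hit), 1L)
    start_idx <- which(tr$pos == hit$start[1])
    end_idx <- which(tr$pos == hit$end[1])
    expect_lte(abs(start_idx - min(planted_idx)), window / 2)
    expect_lte(abs(end_idx - max(planted_idx)), window / 2)
  }
})
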