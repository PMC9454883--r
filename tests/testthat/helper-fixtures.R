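# Shared fixture builders. Everything is generated in code at test time.

# quick marker map on one or more chromosomes, non-ambiguous alleles
mk_map <- function(n, chr = "1", pos = NULL, ref = "A", alt = "G") {
  if (is.null(pos)) pos <- seq_len(n) * 100L
  marker_map(chr = rep_len(chr, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n))
}

# genotype matrix from a plain matrix (samples x markers)
mk_gm <- function(geno, map = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  if (is.null(map)) map <- mk_map(ncol(geno))
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  genotype_matrix(geno, samples, map)
}

# random panel pair with controlled per-call error and missing rate
rand_pair <- function(n = 20, m = 50, err = 0.1, miss = 0, seed = 1) {
  set.seed(seed)
  map <- mk_map(m)
  truth <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  imp <- truth
  flip <- runif(n * m) < err
  imp[flip] <- (imp[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
  if (miss > 0) {
    truth[runif(n * m) < miss] <- NA_integer_
    imp[runif(n * m) < miss] <- NA_integer_
  }
  panel_pair(mk_gm(truth, map), mk_gm(imp, map))
}

# haplotype set built by hand
mk_haps <- function(haps, map, freq = NULL) {
  structure(list(haps = haps, map = map, freq = freq),
            class = "haplotype_set")
}

# independent Pearson correlation oracle (raw-sum formula)
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# path to the shipped benchmark region table
benchmark_regions <- function() {
  read_region_table(system.file("extdata", "hanwoo_poor_regions.tsv",
                                package = "imputeval"))
}
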