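#' Marker map
#'
#' A per-marker table describing biallelic SNPs: chromosome label, physical
#' position (1-based, base pairs), marker id and REF/ALT alleles. Positions
#' must be strictly increasing within a chromosome and every marker must be
#' biallelic with REF distinct from ALT.
#'
#' @param chr chromosome labels (autosomes are "1".."29" for cattle).
#' @param pos 1-based physical positions in base pairs.
#' @param id marker identifiers; generated as `chr:pos` when `NULL`.
#' @param ref,alt single-character REF and ALT alleles (A, C, G or T).
#'
#' @return A `data.frame` of class `marker_map` with columns
#'   `chr`, `pos`, `id`, `ref`, `alt`.
#' @export
marker_map <- function(chr, pos, id = NULL, ref, alt) {
  chr <- as.character(chr)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(pos)
  if (length(chr) == 1L) chr <- rep(chr, n)
  if (length(ref) == 1L) ref <- rep(ref, n)
  if (length(alt) == 1L) alt <- rep(alt, n)
  if (length(chr) != n || length(ref) != n || length(alt) != n)
    stop("marker_map: chr, pos, ref, alt must have equal length")
  if (is.null(id)) id <- paste(chr, pos, sep = ":")
  id <- as.character(id)
  bases <- c("A", "C", "G", "T")
  if (n > 0L) {
    if (!all(ref %in% bases) || !all(alt %in% bases))
      stop("marker_map: alleles must be single bases A/C/G/T")
    if (any(ref == alt))
      stop("marker_map: REF and ALT must differ (biallelic markers only)")
    for (ch in unique(chr)) {
      p <- pos[chr == ch]
      if (any(diff(p) <= 0L))
        stop("marker_map: positions must be strictly increasing within chromosome ", ch)
    }
  }
  map <- data.frame(chr = chr, pos = pos, id = id, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  map
}

marker_key <- function(map) paste(map$chr, map$pos, sep = ":")

#' Genotype matrix
#'
#' Container for diploid biallelic genotype calls coded as ALT-allele dosage
#' (0, 1 or 2) with `NA` for missing calls. Rows are samples, columns are
#' markers in the order of the accompanying [marker_map()].
#'
#' @param geno numeric/integer matrix, samples x markers, entries in
#'   `{0, 1, 2, NA}`.
#' @param samples sample identifiers (defaults to `rownames(geno)`).
#' @param map a [marker_map()] with one row per column of `geno`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `samples`, `map`.
#' @export
genotype_matrix <- function(geno, samples = rownames(geno), map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  samples <- as.character(samples)
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (nrow(geno) != length(samples))
    stop("genotype_matrix: ", length(samples), " sample ids for ",
         nrow(geno), " rows")
  if (ncol(geno) != nrow(map))
    stop("genotype_matrix: ", nrow(map), " markers in map for ",
         ncol(geno), " columns")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype_matrix: non-missing calls must be dosages 0, 1 or 2")
  dimnames(geno) <- list(samples, map$id)
  structure(list(geno = geno, samples = samples, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_markers(x), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chr), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Panel dimensions
#'
#' @param x a `genotype_matrix`.
#' @return Number of samples / markers.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_markers <- function(x) ncol(x$geno)

subset_samples <- function(x, idx) {
  genotype_matrix(x$geno[idx, , drop = FALSE], x$samples[idx], x$map)
}

subset_markers <- function(x, idx) {
  map <- x$map[idx, , drop = FALSE]
  class(map) <- c("marker_map", "data.frame")
  genotype_matrix(x$geno[, idx, drop = FALSE], x$samples, map)
}

#' Per-marker ALT allele frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing calls; markers with no
#' non-missing call get `NA`.
#'
#' @param x a `genotype_matrix`.
#' @return Numeric vector, one value per marker.
#' @export
alt_freq <- function(x) colMeans(x$geno, na.rm = TRUE) / 2

#' @rdname alt_freq
#' @export
marker_maf <- function(x) {
  p <- alt_freq(x)
  pmin(p, 1 - p)
}

#' Panel pair
#'
#' A truth panel and an imputed panel harmonized to identical samples and
#' markers in identical order; the substrate of all accuracy metrics.
#'
#' @param truth,imputed `genotype_matrix` objects with identical sample ids
#'   and identical marker maps.
#' @return An object of class `panel_pair`.
#' @export
panel_pair <- function(truth, imputed) {
  if (!identical(truth$samples, imputed$samples))
    stop("panel_pair: sample ids differ between truth and imputed")
  if (!identical(marker_key(truth$map), marker_key(imputed$map)))
    stop("panel_pair: marker maps differ between truth and imputed")
  if (!identical(truth$map$ref, imputed$map$ref) ||
      !identical(truth$map$alt, imputed$map$alt))
    stop("panel_pair: REF/ALT alleles differ; harmonize panels first")
  structure(list(truth = truth, imputed = imputed), class = "panel_pair")
}

#' @export
print.panel_pair <- function(x, ...) {
  cat("panel_pair:", n_samples(x$truth), "samples x",
      n_markers(x$truth), "markers\n")
  invisible(x)
}
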