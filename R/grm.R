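#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum p (1 - p)), where Z is the dosage matrix centered by
#' twice the ALT frequency and the sum runs over polymorphic markers only.
#' Missing calls are imputed to the per-marker mean dosage before
#' centering. Monomorphic markers (p = 0 or 1) are excluded from both
#' numerator and denominator.
#'
#' @param x a `genotype_matrix`.
#' @param freqs optional per-marker ALT frequencies to center with (e.g.
#'   from the truth panel); defaults to frequencies computed from `x`.
#' @return Object of class `grm`: list with `mat` (n x n symmetric),
#'   `samples`, `n_markers` (polymorphic markers used) and `freq_source`
#'   (`"panel"` or `"supplied"`).
#' @export
compute_grm <- function(x, freqs = NULL) {
  g <- x$geno
  src <- if (is.null(freqs)) "panel" else "supplied"
  p <- if (is.null(freqs)) alt_freq(x) else as.numeric(freqs)
  if (length(p) != ncol(g)) stop("compute_grm: one frequency per marker required")
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("compute_grm: no polymorphic markers")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0L)) g[is.na(g[, j]), j] <- mu[j]
  z <- sweep(g, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  mat <- tcrossprod(z) / denom
  dimnames(mat) <- list(x$samples, x$samples)
  structure(list(mat = mat, samples = x$samples, n_markers = sum(poly),
                 freq_source = src), class = "grm")
}

#' Sum-of-squares deviation between two GRMs
#'
#' Sum over all n^2 elements (diagonal included) of the squared elementwise
#' difference; symmetric in its arguments.
#'
#' @param g1,g2 `grm` objects over the same samples in the same order.
#' @return Scalar sum of squares.
#' @export
grm_ss_deviation <- function(g1, g2) {
  stopifnot(inherits(g1, "grm"), inherits(g2, "grm"))
  if (!identical(g1$samples, g2$samples))
    stop("grm_ss_deviation: sample lists differ")
  sum((g1$mat - g2$mat)^2)
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs of the relationship matrix; sample coordinates are the
#' eigenvectors scaled by the square root of their eigenvalue (negative
#' eigenvalues, possible in near-singular GRMs, scale by 0).
#'
#' @param g a `grm`.
#' @param k number of components.
#' @return List with `values` (length k, non-increasing) and `coords`
#'   (n x k matrix, samples in rows).
#' @export
grm_pca <- function(g, k = 2L) {
  stopifnot(inherits(g, "grm"))
  if (k <= 0) stop("grm_pca: k must be positive")
  n <- length(g$samples)
  if (k > n) stop("grm_pca: k exceeds sample count")
  ee <- eigen(g$mat, symmetric = TRUE)
  vals <- ee$values[seq_len(k)]
  coords <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals, 0)), nrow = k)
  rownames(coords) <- g$samples
  list(values = vals, coords = coords)
}

#' Write a GRM as a tab-separated square matrix
#'
#' @param g a `grm`.
#' @param path output path; the header row carries the sample ids.
#' @return `path`, invisibly.
#' @export
write_grm <- function(g, path) {
  utils::write.table(g$mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
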