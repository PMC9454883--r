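#' Region-scan parameters
#'
#' Tuning of the poorly-imputed-region scan: the running-median window (in
#' SNPs, odd), the genome-wide percentile defining the low-concordance
#' cutoff (0.1 means the 0.1th percentile, i.e. quantile 0.001), the
#' maximum gap in base pairs joining flagged SNPs into one region, and the
#' minimum flagged-SNP count a reported region must contain.
#'
#' @param window running-median window size in SNPs (odd, >= 1).
#' @param percentile percentile in (0, 100\].
#' @param max_gap_bp maximum within-region gap in bp (> 0).
#' @param min_snps minimum flagged SNPs per reported region.
#' @return List of class `scan_parameters`.
#' @export
scan_parameters <- function(window = 1001L, percentile = 0.1,
                            max_gap_bp = 1e6, min_snps = 2L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("scan_parameters: window must be odd and >= 1")
  if (percentile <= 0 || percentile > 100)
    stop("scan_parameters: percentile must lie in (0, 100]")
  if (max_gap_bp <= 0) stop("scan_parameters: max_gap_bp must be positive")
  if (min_snps < 1L) stop("scan_parameters: min_snps must be >= 1")
  structure(list(window = window, percentile = percentile,
                 max_gap_bp = max_gap_bp, min_snps = as.integer(min_snps)),
            class = "scan_parameters")
}

#' Per-marker accuracy track
#'
#' @param chr chromosome labels.
#' @param pos positions (bp); must be sorted increasing within chromosome.
#' @param value per-marker accuracy in \[0, 1\] (e.g. per-SNP concordance).
#' @return data.frame of class `accuracy_track`.
#' @export
accuracy_track <- function(chr, pos, value) {
  chr <- as.character(chr)
  if (length(chr) == 1L) chr <- rep(chr, length(pos))
  stopifnot(length(chr) == length(pos), length(pos) == length(value))
  for (ch in unique(chr)) {
    if (is.unsorted(pos[chr == ch], strictly = TRUE))
      stop("accuracy_track: positions not strictly increasing on chromosome ", ch)
  }
  if (any(!is.na(value) & (value < 0 | value > 1)))
    stop("accuracy_track: values must lie in [0, 1]")
  structure(data.frame(chr = chr, pos = pos, value = value,
                       stringsAsFactors = FALSE),
            class = c("accuracy_track", "data.frame"))
}

shrinking_median <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(v)
  out <- numeric(n)
  if (n >= window) {
    out <- stats::runmed(v, window, endrule = "keep")
    edge <- c(seq_len(h), seq(n - h + 1L, n))
  } else {
    edge <- seq_len(n)
  }
  for (i in edge)
    out[i] <- stats::median(v[max(1L, i - h):min(n, i + h)])
  out
}

#' Running median of an accuracy track
#'
#' Centered per-chromosome running median in windows of `window` SNPs. At
#' chromosome edges the window shrinks to the markers available within the
#' half-width, so edge markers are smoothed over fewer values instead of
#' being discarded; even-count windows use the midpoint of the two central
#' values.
#'
#' @param track an [accuracy_track()].
#' @param window odd window size in SNPs.
#' @return The smoothed `accuracy_track`.
#' @export
running_median_track <- function(track, window = 1001L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("running_median_track: window must be odd and >= 1")
  if (!inherits(track, "accuracy_track"))
    track <- accuracy_track(track$chr, track$pos, track$value)
  out <- track
  for (ch in unique(track$chr)) {
    sel <- track$chr == ch
    out$value[sel] <- shrinking_median(track$value[sel], window)
  }
  out
}

#' Flag SNPs below a genome-wide percentile cutoff
#'
#' The cutoff is the empirical quantile of the smoothed values at
#' `percentile`/100, taken by the nearest-rank rule (the value at rank
#' `ceiling(p n)` of the sorted track); markers with smoothed value less
#' than or equal to the cutoff are flagged.
#'
#' @param smoothed an [accuracy_track()] (normally the running median).
#' @param percentile percentile in (0, 100\].
#' @return List with `cutoff`, logical vector `flagged`, and `n_flagged`.
#' @export
flag_low_snps <- function(smoothed, percentile = 0.1) {
  v <- smoothed$value
  if (length(v) == 0L) stop("flag_low_snps: empty track")
  if (percentile <= 0 || percentile > 100)
    stop("flag_low_snps: percentile must lie in (0, 100]")
  rank <- max(1L, ceiling(percentile / 100 * length(v)))
  cutoff <- sort(v)[rank]
  flagged <- !is.na(v) & v <= cutoff
  list(cutoff = cutoff, flagged = flagged, n_flagged = sum(flagged))
}

#' Merge flagged SNPs into poorly imputed regions
#'
#' Within a chromosome, consecutive flagged SNPs at most `max_gap_bp` apart
#' join one region; a gap strictly greater than `max_gap_bp` starts a new
#' region. Regions containing fewer than `min_snps` flagged SNPs are
#' discarded. Region start/end are the first/last flagged positions
#' (closed interval) and length = end - start.
#'
#' @param flagged data.frame with columns `chr` and `pos` of the flagged
#'   SNPs, sorted by position within chromosome.
#' @param params a [scan_parameters()] (only `max_gap_bp` and `min_snps`
#'   are used).
#' @return data.frame of class `region_table` with columns `chr`, `start`,
#'   `end`, `length`, `n_snps`.
#' @export
merge_regions <- function(flagged, params = scan_parameters()) {
  stopifnot(all(c("chr", "pos") %in% names(flagged)))
  rows <- list()
  for (ch in unique(as.character(flagged$chr))) {
    pos <- flagged$pos[flagged$chr == ch]
    if (is.unsorted(pos)) stop("merge_regions: unsorted positions on ", ch)
    grp <- cumsum(c(1L, as.integer(diff(pos) > params$max_gap_bp)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < params$min_snps) next
      rows[[length(rows) + 1L]] <-
        data.frame(chr = ch, start = min(p), end = max(p),
                   length = max(p) - min(p), n_snps = length(p),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chr = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0), n_snps = integer(0),
               stringsAsFactors = FALSE)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Flagged-SNP counts per chromosome
#'
#' Sums the per-region flagged-SNP counts by chromosome and ranks
#' chromosomes by that count, descending.
#'
#' @param regions a `region_table`.
#' @return data.frame with `chr` and `n_snps`, sorted by `n_snps`
#'   descending.
#' @export
per_chromosome_flag_counts <- function(regions) {
  if (nrow(regions) == 0L)
    return(data.frame(chr = character(0), n_snps = integer(0),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(n_snps ~ chr, data = as.data.frame(regions), FUN = sum)
  agg <- agg[order(-agg$n_snps), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Accuracy profile by distance to the nearest chromosome end
#'
#' Bins markers by `min(pos, length - pos)` at the given bin width and
#' reports the mean accuracy per bin, exposing end-of-chromosome accuracy
#' loss.
#'
#' @param track an [accuracy_track()].
#' @param chr_lengths named numeric vector of chromosome lengths (bp);
#'   every marker position must not exceed its chromosome's length.
#' @param bin_width_bp distance bin width (default 1 Mb).
#' @return data.frame with `dist_low`, `dist_high`, `n_markers`,
#'   `mean_value`.
#' @export
end_distance_profile <- function(track, chr_lengths, bin_width_bp = 1e6) {
  len <- as.numeric(chr_lengths[track$chr])
  if (any(is.na(len)))
    stop("end_distance_profile: missing chromosome length for some markers")
  if (any(track$pos > len))
    stop("end_distance_profile: marker position exceeds stated chromosome length")
  d <- pmin(track$pos, len - track$pos)
  bin <- floor(d / bin_width_bp)
  ub <- sort(unique(bin))
  ok <- !is.na(track$value)
  mv <- tapply(track$value[ok], factor(bin[ok], ub), mean)
  n <- tapply(track$value[ok], factor(bin[ok], ub), length)
  n[is.na(n)] <- 0L
  data.frame(dist_low = ub * bin_width_bp,
             dist_high = (ub + 1L) * bin_width_bp,
             n_markers = as.integer(n), mean_value = as.numeric(mv))
}

#' Full poorly-imputed-region scan
#'
#' Chains the running median, percentile flagging and region merging.
#'
#' @param track an [accuracy_track()] of per-SNP concordance.
#' @param params a [scan_parameters()].
#' @return List with `smoothed` (track), `cutoff`, `flagged` (data.frame of
#'   flagged chr/pos), `regions` (a `region_table`) and `params`.
#' @export
scan_regions <- function(track, params = scan_parameters()) {
  smoothed <- running_median_track(track, params$window)
  fl <- flag_low_snps(smoothed, params$percentile)
  flagged <- smoothed[fl$flagged, c("chr", "pos")]
  regions <- merge_regions(flagged, params)
  list(smoothed = smoothed, cutoff = fl$cutoff, flagged = flagged,
       regions = regions, params = params)
}

#' Read / write a region table
#'
#' Tab-separated region tables with columns `chr`, `start`, `end`,
#' `length`, `n_snps`. `write_region_table()` can prepend `#`-prefixed
#' header comments (e.g. echoing scan parameters).
#'
#' @param path file path.
#' @return `read_region_table()`: a `region_table` data.frame.
#' @export
read_region_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  out$chr <- as.character(out$chr)
  need <- c("chr", "start", "end", "length", "n_snps")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("read_region_table: missing column(s): ", paste(miss, collapse = ", "))
  class(out) <- c("region_table", "data.frame")
  out
}

#' @rdname read_region_table
#' @param regions a `region_table`.
#' @param comments character vector of header comment lines (without `#`).
#' @export
write_region_table <- function(regions, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(as.data.frame(regions), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a region table to BED intervals
#'
#' Region tables use 1-based closed intervals; BED is 0-based half-open,
#' so start becomes `start - 1` and end stays.
#'
#' @param regions a `region_table`.
#' @return data.frame with `chrom`, `chromStart`, `chromEnd`.
#' @export
region_table_to_bed <- function(regions) {
  data.frame(chrom = regions$chr, chromStart = regions$start - 1L,
             chromEnd = regions$end, stringsAsFactors = FALSE)
}
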