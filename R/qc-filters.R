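#' Sample and marker missingness filters
#'
#' Standard panel quality control: samples with more than `max_missing`
#' of their genotypes missing are excluded, and markers with a missing rate
#' above `max_missing` or mapped outside the autosome set are deleted.
#' Both filters use a strict inequality, so a value exactly at the
#' threshold is kept. Survivor order is preserved. The pipeline applies
#' the sample filter first, then the marker filter.
#'
#' @param x a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction; default 0.10 for
#'   samples and 0.20 for markers.
#' @param autosomes chromosome labels retained by the marker filter;
#'   defaults to the 29 cattle autosomes.
#' @return The filtered `genotype_matrix`. Removing everything produces an
#'   empty matrix with a warning, not an error.
#' @export
filter_samples <- function(x, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- rowMeans(is.na(x$geno))
  miss[is.nan(miss)] <- 0          # zero-marker panel: nothing is missing
  keep <- miss <= max_missing
  if (!any(keep)) warning("filter_samples: all samples removed")
  subset_samples(x, which(keep))
}

#' @rdname filter_samples
#' @export
filter_markers <- function(x, max_missing = 0.20,
                           autosomes = as.character(1:29)) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(x$geno))
  miss[is.nan(miss)] <- 0          # zero-sample panel: nothing is missing
  keep <- miss <= max_missing & x$map$chr %in% autosomes
  if (!any(keep)) warning("filter_markers: all markers removed")
  subset_markers(x, which(keep))
}

#' Default hard-filter thresholds for sequence variant sites
#'
#' The standard short-read variant-calling hard filters: sites are removed
#' when QUAL < 50, QD < 2.0, MQ < 40.0, FS > 100.0, MQRankSum < -8.0,
#' ReadPosRankSum < -20.0, ExcessHet > 54.69, or variant missingness > 0.2.
#'
#' @return Named list of thresholds consumed by [apply_site_hard_filters()].
#' @export
site_filter_thresholds <- function() {
  list(qual_min = 50, qd_min = 2.0, mq_min = 40.0, fs_max = 100.0,
       mqranksum_min = -8.0, readposranksum_min = -20.0,
       excesshet_max = 54.69, missing_max = 0.2)
}

# rule table: annotation column, threshold name, direction of failure
.site_rules <- data.frame(
  field = c("QUAL", "QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum",
            "ExcessHet", "missingness"),
  thr = c("qual_min", "qd_min", "mq_min", "fs_max", "mqranksum_min",
          "readposranksum_min", "excesshet_max", "missing_max"),
  fail_low = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

#' Apply variant-site hard filters
#'
#' Evaluates each site annotation record against the hard-filter rules and
#' returns a pass/fail verdict together with all violated rule codes. An
#' absent (`NA`) annotation does not trigger its rule unless
#' `strict_absent = TRUE`.
#'
#' @param records data.frame of per-site annotations; recognised columns are
#'   `QUAL`, `QD`, `MQ`, `FS`, `MQRankSum`, `ReadPosRankSum`, `ExcessHet`
#'   and `missingness` (fraction in \[0, 1\]). Any may be omitted.
#' @param thresholds threshold list, see [site_filter_thresholds()].
#' @param strict_absent fail a rule when its annotation is absent.
#' @return data.frame with logical `pass` and a comma-separated `reasons`
#'   string of violated rule codes ("" when passing).
#' @export
apply_site_hard_filters <- function(records,
                                    thresholds = site_filter_thresholds(),
                                    strict_absent = FALSE) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (!is.null(records$missingness)) {
    ms <- records$missingness[!is.na(records$missingness)]
    if (length(ms) && (any(ms < 0) || any(ms > 1)))
      stop("apply_site_hard_filters: missingness must lie in [0, 1]")
  }
  fail <- matrix(FALSE, n, nrow(.site_rules),
                 dimnames = list(NULL, .site_rules$field))
  for (k in seq_len(nrow(.site_rules))) {
    fld <- .site_rules$field[k]
    if (!fld %in% names(records)) next
    v <- records[[fld]]
    if (!is.numeric(v))
      stop("apply_site_hard_filters: non-numeric annotation '", fld, "'")
    thr <- thresholds[[.site_rules$thr[k]]]
    bad <- if (.site_rules$fail_low[k]) v < thr else v > thr
    bad[is.na(v)] <- strict_absent
    fail[, k] <- bad
  }
  reasons <- apply(fail, 1L, function(r) paste(colnames(fail)[r], collapse = ","))
  data.frame(pass = !apply(fail, 1L, any), reasons = reasons,
             stringsAsFactors = FALSE)
}
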