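#' Harmonize marker alleles against a reference map
#'
#' Matches target markers to a reference map by chromosome and position and
#' reconciles REF/ALT coding. Markers with an exact REF/ALT match are kept
#' unchanged; markers whose alleles are swapped relative to the reference
#' (target REF = reference ALT and vice versa) are kept with every dosage d
#' recoded to 2 - d and the stored alleles set to the reference coding.
#' Markers whose allele pair is strand-ambiguous (A/T or C/G) are dropped,
#' as are markers with any other allele configuration or without a
#' positional match in the reference.
#'
#' @param target a `genotype_matrix` to recode.
#' @param reference_map a [marker_map()] giving the desired allele coding.
#' @return List with elements `matrix` (the harmonized `genotype_matrix`)
#'   and `report` (a `harmonization_report` data.frame of disposition
#'   counts, which always sum to the input marker count).
#' @export
harmonize_markers <- function(target, reference_map) {
  if (!inherits(reference_map, "marker_map"))
    stop("reference_map must be a marker_map")
  tkey <- marker_key(target$map)
  rkey <- marker_key(reference_map)
  if (anyDuplicated(tkey))
    stop("harmonize_markers: duplicate chromosome+position in target map")
  if (anyDuplicated(rkey))
    stop("harmonize_markers: duplicate chromosome+position in reference map")

  hit <- match(tkey, rkey)
  m <- n_markers(target)
  disposition <- rep("dropped_unmatched", m)
  matched <- !is.na(hit)

  amb <- c("A:T", "T:A", "C:G", "G:C")
  t_pair <- paste(target$map$ref, target$map$alt, sep = ":")
  r_ref <- r_alt <- rep(NA_character_, m)
  r_ref[matched] <- reference_map$ref[hit[matched]]
  r_alt[matched] <- reference_map$alt[hit[matched]]

  same <- matched & target$map$ref == r_ref & target$map$alt == r_alt
  swap <- matched & target$map$ref == r_alt & target$map$alt == r_ref
  is_amb <- matched & t_pair %in% amb
  disposition[matched] <- "dropped_mismatch"
  disposition[same] <- "kept_unchanged"
  disposition[swap] <- "kept_flipped"
  disposition[is_amb] <- "dropped_ambiguous"   # ambiguity trumps same/swap

  keep <- disposition %in% c("kept_unchanged", "kept_flipped")
  flip <- disposition == "kept_flipped"
  geno <- target$geno
  if (any(flip)) geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  map <- target$map
  map$ref[flip] <- r_ref[flip]
  map$alt[flip] <- r_alt[flip]
  class(map) <- c("marker_map", "data.frame")
  out_map <- map[keep, , drop = FALSE]
  class(out_map) <- c("marker_map", "data.frame")
  out <- genotype_matrix(geno[, keep, drop = FALSE], target$samples, out_map)

  cats <- c("kept_unchanged", "kept_flipped", "dropped_ambiguous",
            "dropped_mismatch", "dropped_unmatched")
  report <- data.frame(category = cats,
                       n = as.integer(table(factor(disposition, cats))),
                       stringsAsFactors = FALSE)
  class(report) <- c("harmonization_report", "data.frame")
  stopifnot(sum(report$n) == m)
  list(matrix = out, report = report)
}

#' Write a harmonization report as a tab-separated table
#'
#' @param report a `harmonization_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect two panels into a comparable pair
#'
#' Restricts a truth panel and an imputed panel to their shared samples and
#' shared markers (matched by chromosome and position), both in truth-panel
#' order, and returns the resulting [panel_pair()]. Harmonization of allele
#' coding is assumed to have been applied already.
#'
#' @param truth,imputed `genotype_matrix` objects.
#' @return A `panel_pair`.
#' @export
intersect_panels <- function(truth, imputed) {
  shared_samples <- truth$samples[truth$samples %in% imputed$samples]
  if (length(shared_samples) == 0L)
    stop("intersect_panels: no shared samples between panels")
  tkey <- marker_key(truth$map)
  ikey <- marker_key(imputed$map)
  shared_markers <- tkey[tkey %in% ikey]
  if (length(shared_markers) == 0L)
    stop("intersect_panels: no shared markers between panels")
  t2 <- subset_samples(truth, match(shared_samples, truth$samples))
  t2 <- subset_markers(t2, match(shared_markers, tkey))
  i2 <- subset_samples(imputed, match(shared_samples, imputed$samples))
  i2 <- subset_markers(i2, match(shared_markers, ikey))
  panel_pair(t2, i2)
}
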