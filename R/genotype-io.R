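#' Read a genotype panel from VCF
#'
#' Parses a VCF 4.x file into a [genotype_matrix()]. Diploid GT pairs are
#' mapped to ALT-allele dosage; half-missing or fully missing calls become
#' the missing sentinel (`NA`). Marker order is preserved.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param field genotype source: `"GT"` (hard calls, default) or `"DS"`
#'   (posterior dosages, rounded to the nearest integer call).
#' @param strict when `TRUE` (default) a multiallelic record aborts the read
#'   with the offending marker named; when `FALSE` such records are dropped
#'   with a warning.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, field = c("GT", "DS"), strict = TRUE) {
  field <- match.arg(field)
  if (!file.exists(path)) stop("read_genotypes: no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("read_genotypes: malformed VCF '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    ids <- fix[multi, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste(fix[multi, "CHROM"], fix[multi, "POS"], sep = ":")[is.na(ids) | ids == "."]
    if (strict)
      stop("read_genotypes: multiallelic record(s): ",
           paste(utils::head(ids, 5L), collapse = ", "))
    warning("read_genotypes: dropping ", sum(multi), " multiallelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- vcf@fix
  }
  ids <- fix[, "ID"]
  bad_id <- is.na(ids) | ids == "."
  ids[bad_id] <- paste(fix[bad_id, "CHROM"], fix[bad_id, "POS"], sep = ":")
  map <- marker_map(chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = ids, ref = fix[, "REF"], alt = fix[, "ALT"])
  if (field == "GT") {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- gt_to_dosage(gt)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- round(ds)
    if (any(!is.na(dos) & !(dos %in% 0:2)))
      stop("read_genotypes: DS values outside [0, 2]")
  }
  # extract.gt returns markers x samples; the container is samples x markers
  genotype_matrix(t(dos), samples = colnames(dos), map = map)
}

# "0/0" -> 0, "0|1" -> 1, "1/1" -> 2; any "." in the call -> NA
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  vals <- gt[clean]
  if (length(vals)) {
    alleles <- strsplit(vals, "[/|]")
    bad <- lengths(alleles) != 2L
    if (any(bad))
      stop("read_genotypes: non-diploid GT value(s), e.g. '", vals[bad][1L], "'")
    d[clean] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    if (any(!unlist(alleles) %in% c("0", "1")))
      stop("read_genotypes: GT alleles other than 0/1 found")
  }
  d
}

#' Write a genotype panel to VCF
#'
#' Emits a minimal VCF 4.2 file with hard GT calls such that
#' `read_genotypes(write_genotypes(x, f))` reproduces `x` exactly
#' (dosages, missingness pattern and marker map).
#'
#' @param x a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  map <- x$map
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=imputeval",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(0)
  if (nrow(map) > 0L) {
    g <- x$geno                              # samples x markers
    gt <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    gt[ok] <- gt_code[g[ok] + 1L]
    cols <- c(list(map$chr, map$pos, map$id, map$ref, map$alt,
                   ".", ".", ".", "GT"),
              lapply(seq_len(nrow(g)), function(i) gt[i, ]))
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
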