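Package: imputeval
Title: Evaluation of Genotype Imputation Accuracy in Livestock Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate the accuracy of genotype imputation up to
    whole-genome sequence level. Provides VCF-backed genotype containers
    with hard-filter and missingness quality control, REF/ALT allele
    harmonization between panels, concordance and correlation metrics at
    the sample, marker and genotype-class level, allele-frequency-binned
    concordance, fixed-marker (spurious segregation) reports, IMPUTE-style
    info-score evaluation, genomic relationship matrix comparison, and a
    running-median genome scan that detects poorly imputed chromosomal
    regions. A haplotype-mosaic simulator with a controllable genotype
    error model (including minor-allele-frequency dependence, planted
    low-accuracy regions and chromosome-end error gradients) and a naive
    nearest-haplotype imputer support end-to-end evaluation experiments on
    synthetic panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
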