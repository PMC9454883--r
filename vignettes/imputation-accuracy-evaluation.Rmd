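---
title: "Evaluating genotype imputation accuracy with imputeval"
author: "imputeval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype imputation accuracy with imputeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeval)
```

## The problem

Sequence-level genotype imputation takes animals genotyped on a cheap
low-density array (tens of thousands of SNPs) and infers the millions of
variants segregating in a sequenced reference panel. Whether the imputed
genotypes are usable depends on how, and where, imputation fails: accuracy
differs by sample, by marker, by genotype class (heterozygotes are by far
the hardest to impute), by allele frequency, and along the genome —
chromosome ends and haplotype-diverse regions such as the MHC are
notoriously poor. A single overall number hides all of that. `imputeval`
computes the full multi-level accuracy decomposition for a pair of panels
and, because real sequenced cattle panels are rarely redistributable, ships
a simulator that generates panel pairs whose error structure is known
exactly, so every statistic can be validated against the parameters that
generated the data.

## Data model and quality control

Genotypes live in a `genotype_matrix`: samples x markers ALT-dosage calls
in {0, 1, 2, NA} plus a `marker_map` (chromosome, 1-based position, id,
REF/ALT). Only biallelic SNPs with single-base alleles are representable;
positions are strictly increasing within a chromosome, and duplicated
chromosome+position keys are rejected outright rather than silently
resolved — downstream harmonization matches markers by position and must
be a bijection. VCF input goes through `vcfR`; writing emits a minimal
VCF 4.2 with hard GT calls such that a write/read round trip is exact.

Quality control mirrors common sequence-panel practice:

* `filter_samples()` drops samples with more than 10% missing genotypes,
  `filter_markers()` drops markers with more than 20% missingness or
  outside the 29 cattle autosomes. Both thresholds are strict
  inequalities — a value exactly at the threshold is kept — and the
  pipeline convention is samples first, then markers (the orders do not
  commute once anything is removed).
* `apply_site_hard_filters()` implements the standard short-read hard
  filters (QUAL >= 50; QD >= 2; MQ >= 40; FS <= 100; MQRankSum >= -8;
  ReadPosRankSum >= -20; ExcessHet <= 54.69; site missingness <= 0.2).
  An absent annotation passes its rule by default, matching variant-calling
  convention; `strict_absent = TRUE` reverses that.

`harmonize_markers()` reconciles allele coding between panels matched by
chromosome+position: exact REF/ALT matches pass, swapped coding is kept
with dosages recoded d to 2 - d, A/T and C/G pairs are dropped as
strand-unresolvable, and anything else is dropped as a mismatch. The
disposition counts always sum to the input marker count, and applying the
swap twice is the identity — both are enforced by tests.

## Accuracy statistics

All comparisons are pairwise complete: a call missing in either panel is
excluded from the denominator (how missing calls were handled upstream is
exactly the kind of question the `panel_discordance()` strata are for).
Summaries report, per sample and per marker, the concordance rate and the
Pearson correlation of dosages. Markers with zero variance in either panel
have no defined correlation; they are excluded from mean-R summaries and
counted separately, so summaries over panels with many rare or fixed
variants remain interpretable.

The genotype confusion table is row-normalized by the true genotype class,
so each row of the percentage view sums to 100 and the diagonal is the
class-specific concordance; its trace over the counts equals the overall
CR, an accounting identity the tests assert on random panels.
Allele-frequency-binned concordance uses the truth ALT frequency on
[0, 1] in bins of width 0.01 — bins are [kw, (k+1)w) with the last bin
closed, empty bins are flagged rather than zero-filled — and a folded
minor-allele-frequency view is available (`by = "maf"`).

The info score is the IMPUTE-style ratio of observed to expected
statistical information about the allele frequency computed from genotype
posterior triples; it is 1 by convention when the estimated frequency is
0 or 1 and clamped to [0, 1]. `info_filter_evaluation()` quantifies how
well an info cutoff (retention rule info >= cutoff; strictness
configurable) predicts realized concordance.

The GRM uses VanRaden method 1 with frequencies from the truth panel by
default (the frequency source is recorded in the object); missing calls
are mean-imputed per marker and monomorphic markers are excluded from
numerator and denominator. The deviation between two GRMs is the sum of
squared differences over all n^2 elements, diagonal included.

## The region scan

`scan_regions()` detects poorly imputed regions from the per-SNP
concordance track in three steps, each with an explicit convention:

1. **Running median** per chromosome in windows of `window` SNPs
   (default 1001, odd). At chromosome edges the window shrinks to the
   markers available within the half-width instead of discarding edge
   markers — the ends of chromosomes are precisely where accuracy is
   worst, so a scan blind there would be useless. Even-count edge windows
   take the midpoint of the two central values.
2. **Flagging** at a genome-wide (not per-chromosome) empirical quantile
   of the smoothed values — one cutoff for the whole genome — using the
   nearest-rank rule for reproducibility across numeric environments,
   with a less-than-or-equal comparison. On a constant track this flags
   everything; that degenerate behavior is documented and kept in the
   file-level scan, while the evaluation pipeline treats a perfectly
   concordant track as having no poorly imputed regions.
3. **Merging**: consecutive flagged SNPs more than `max_gap_bp`
   (default 1 Mb, strictly greater) apart start a new region; regions
   with fewer than `min_snps` (default 2) flagged SNPs are discarded.
   Regions are closed 1-based intervals from the first to the last
   flagged position with `length = end - start` — the convention is
   validated against every row of the published benchmark region table
   shipped under `inst/extdata/`, as are the per-chromosome flagged-SNP
   sums and the chromosomes of the five longest regions. BED export
   converts explicitly to 0-based half-open.

`end_distance_profile()` bins markers by distance to the nearest
chromosome end and reports mean accuracy per bin, making end-of-chromosome
degradation visible directly.

## The simulator

`simulate_panel_set()` builds the study the evaluation assumes:

* **Founders**: per-marker ALT frequencies from a Beta(0.3, 0.3) spectrum
  by default — U-shaped, so the 0.01-wide frequency bins at both edges are
  populated, which is where imputation behavior is most interesting — with
  a configured fraction (default 0.33) forced monomorphic, emulating the
  roughly one-third of sequence-panel markers fixed within a single breed.
  Haplotypes are drawn independently per marker given the frequency.
* **Descendants**: each of the two haplotypes per sample is a mosaic of
  founder haplotypes switching template with probability `switch_rate`
  per marker interval (geometric segment lengths). This creates LD and
  relatedness structure sufficient for haplotype matching without a
  coalescent simulator; it does not reproduce a realistic site-frequency
  spectrum, pedigree structure, or fine-scale LD decay, so passing tests
  demonstrate correctness of the metrics, not biological realism of any
  particular accuracy level.
* **Error injection**: every non-missing call is re-drawn from the row of
  a 3x3 genotype transition matrix for its true genotype. The default
  matrix has class concordances of about 94/90/98 percent
  (hom-REF/het/hom-ALT), the regime of within-breed sequence imputation
  with a small reference panel. Off-diagonal (error) mass is scaled per
  marker by three optional modifiers — a MAF slope (common variants worse,
  the pattern real panels show), planted bad regions, and a chromosome-end
  gradient `1 + strength * exp(-distance/scale)` — capped so error mass
  never exceeds 0.95, then the diagonal is restored. The effective row is
  emitted as the call's posterior triple, so info scores computed from the
  posteriors are consistent with realized confusion frequencies (real info
  scores come from the imputation software; emitting them from the
  generator is what makes them well defined here).
* **Fixed markers** are copied error-free by the transition channel;
  spurious segregation at truth-monomorphic markers is a separate channel
  (`inject_spurious_segregation()`) with its own rate (default 0.31) and
  mean imputed MAF (default 0.012, realized as `max(1, round(2Nf))`
  minor-allele copies at a drawn frequency f so the mean tracks the scale
  without truncation bias). Real panels show exactly this dissociation:
  fixed-SNP concordance is far higher than the hom-REF confusion row, and
  wrong calls at fixed sites arise from out-of-breed reference variation
  rather than from the within-class error process.
* **Masking**: `mask_to_density()` retains a uniform random
  `round(keep_fraction * m)` marker subset (order preserving, nestable),
  emulating array-inside-sequence marker nesting.

Everything is driven by a single integer seed; identical configurations
produce byte-identical output bundles, which the tests assert at file
level.

## The naive imputer and the composition experiment

`naive_reference_imputer()` is a deliberately simple stand-in for
haplotype-based imputation software (it is not calibrated to any real
tool): within windows of reference markers, each sample's diplotype is
approximated greedily by the two reference haplotypes minimizing dosage
mismatch on the observed markers, and unobserved markers are copied from
the chosen pair. Ties resolve to the first haplotype, which makes
reference order meaningful; `reference_composition_experiment()` exploits
this by listing diverged haplotypes first in the combined panel, so the
combined reference can only lose, never spuriously gain, relative to the
within-population panel. The experiment reproduces, by construction, the
qualitative finding that drives real reference-panel design: a small
related reference beats a much larger diverged one, combining them adds
nothing over the related panel alone, and adding even a small related
subset to a diverged pool recovers a large share of the lost accuracy.

## Numerical choices and degenerate inputs

* Missingness filters keep values exactly at the threshold (strict
  inequalities); removing all samples or markers warns instead of erroring.
* Correlation needs at least two compared calls and nonzero variance on
  both sides; otherwise it is undefined (`NA`), never coerced to 0.
* `impute_info_score()` validates that posterior triples sum to 1 within
  1e-6 and drops rows with missing posteriors.
* The error-model cap (off-diagonal mass <= 0.95 after modifiers) keeps
  every effective transition row a proper distribution no matter how
  aggressive the planted multipliers are.
* Region merging on an empty flagged set returns an empty region table;
  a track position beyond its stated chromosome length is a data error.
* The nearest-rank quantile (`ceiling(p n)`-th order statistic) avoids
  interpolation differences between numeric environments.

## Problem sizes

The shipped tests run the generator at a few hundred to a few thousand
markers and tens to ~140 samples: large enough that binomial parameter-
recovery checks operate on at least 10,000 calls per genotype class and
the planted-region scan has hundreds of markers inside the planted
interval, small enough that the full suite runs in well under a minute.
`scripts/acceptance.R` uses the default configuration (3 chromosomes x
2,000 markers, 136 samples) for the end-to-end pipeline and five
replicate seeds for the composition experiment. These sizes are the
package's validation conditions, not limits: every operation scales to
panels orders of magnitude larger.

## Known limitations

* The simulator's mosaic model has no mutation, no explicit pedigree and
  a single global switch rate; accuracy levels it produces are controlled,
  not calibrated to any particular imputation software or breed.
* The naive imputer ignores genetic distance within windows and performs
  no probabilistic phasing; it exists to rank reference compositions, not
  to estimate achievable accuracies.
* Harmonization never attempts strand flipping of unambiguous pairs or
  liftover between assemblies; markers that disagree after the swap rule
  are dropped.
* Info scores are computed from generator-emitted posteriors; applying
  `info_filter_evaluation()` to scores from external software assumes that
  software's posteriors are calibrated.
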