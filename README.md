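# imputeval

Evaluation of genotype imputation accuracy for dense (up to
whole-genome-sequence) livestock panels.

Genotype imputation infers untyped genotypes in individuals genotyped on a
low-density SNP array from a reference panel of densely genotyped or
sequenced haplotypes. Before imputed genotypes are used for genomic
prediction or association mapping, their accuracy has to be quantified —
overall, per animal, per marker, per genotype class and per allele-frequency
bin — and regions of the genome where imputation systematically fails have
to be mapped. `imputeval` packages that whole evaluation workflow for
researchers in animal (and other) genetics who compare a truth panel with
an imputed panel in VCF form, together with a haplotype-mosaic simulator
that generates panels with a fully controlled error structure for method
validation.

## What it computes

For a harmonized pair of panels (truth *X*, imputed *Y*, ALT-dosage coded
0/1/2 over *N* samples x *M* markers, compared over pairwise non-missing
calls):

* **Concordance rate** CR = #{x = y} / #compared, overall and as
  per-sample / per-marker vectors with min/mean/max summaries and
  threshold-exceedance fractions (share of markers with CR < 0.9).
* **Pearson correlation** R between dosage vectors, per sample and per
  marker; zero-variance vectors are reported as undefined and counted.
* **Genotype confusion table**: 3x3 counts of true x imputed genotype
  class, row-normalized to percentages; the heterozygote error rate
  (100 minus the het-row diagonal) is the hardest-class summary.
* **Allele-frequency-binned concordance** in bins of width 0.01, and the
  correlation between true and imputed allele frequencies.
* **Fixed-SNP report**: markers monomorphic in truth, the fraction that
  spuriously segregate after imputation, their mean imputed MAF, and the
  concordance on the monomorphic set.
* **IMPUTE-style info score** per marker from genotype posteriors,
  info = 1 - sum(f_i - e_i^2) / (2N theta (1 - theta)) with
  e = P(het) + 2 P(homALT), f = P(het) + 4 P(homALT),
  theta = sum(e)/(2N), and an evaluation of info-cutoff filtering against
  realized concordance.
* **GRM comparison**: VanRaden method-1 genomic relationship matrices
  G = ZZ' / (2 sum p(1-p)), their elementwise sum-of-squares deviation
  and principal components.
* **Poorly imputed region scan**: per-chromosome running median of the
  per-SNP concordance track (default window 1001 SNPs), genome-wide
  nearest-rank percentile cutoff (default the 0.1th percentile), merging
  of flagged SNPs less than 1 Mb apart into regions with at least two
  SNPs, plus an accuracy-versus-distance-to-chromosome-end profile.

The simulator (`simulate_panel_set()` and friends) generates founder
haplotypes from a configurable allele-frequency spectrum, mosaic
descendants with geometric recombination segments, density-masked targets,
and an "imputed" panel drawn from a 3x3 genotype transition matrix with
optional MAF-dependent error, planted low-accuracy regions and
chromosome-end error gradients — emitting the genotype posteriors it used
so info scores are well defined. A deliberately naive nearest-haplotype
imputer supports reference-panel composition experiments
(`reference_composition_experiment()`).

## Worked example

```r
library(imputeval)
cfg <- simulation_config(seed = 42)      # 3 chromosomes x 2000 markers, 136 samples
sim <- simulate_panel_set(cfg)
pair <- intersect_panels(sim$truth, sim$imputed)
concordance(pair)
#> overall concordance: 0.9679 (136 samples, 6000 markers)
genotype_confusion(pair)
#> genotype confusion (row %):
#>         imputed
#> true     homREF   het homALT
#>   homREF  97.58  2.29   0.12
#>   het      2.49 89.33   8.17
#>   homALT   0.03  1.48  98.49
#> heterozygote error rate: 10.67% (n = 816000 calls)
```

The overall concordance of 96.8% and heterozygote error of 10.7% recover
the default error model (het-row diagonal 89.53%); heterozygotes are the
hardest class, as in real imputation. Scanning the per-SNP concordance
track flags the least-concordant stretches of the simulated genome:

```r
conc <- concordance(pair)
scan <- scan_regions(accuracy_track(conc$per_snp$chr, conc$per_snp$pos, conc$per_snp$cr),
                     scan_parameters(window = 101, percentile = 1))
head(as.data.frame(scan$regions), 3)
#>   chr    start      end  length n_snps
#> 1   1  7473944  8710687 1236743      5
#> 2   1 10648994 11085198  436204      3
#> 3   1 14571614 15433597  861983     15
```

Region intervals are 1-based and closed, with `length = end - start`.

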