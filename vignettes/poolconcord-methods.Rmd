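---
title: "Evaluating pooled sequencing against individual genotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pooled sequencing against individual genotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolconcord)
```

## The problem

Germplasm banks hold far more accessions than anyone can afford to
genotype plant by plant.  Pool-seq — sequencing one library made from
the pooled tissue of many plants — costs a fraction of individual
genotyping (ind-seq), but returns only allele *read counts*, not
genotypes.  Whether pooled allele-frequency estimates are good enough to
replace individual ones depends on design choices: how many plants to
pool, how hard to filter on missing data (MD), how deep to sequence, and
where to set the minor-allele-frequency (MAF) cutoff.

`poolconcord` implements a complete evaluation pipeline for that
question on DArT-style SNP reports: a score report (markers x
individuals, genotype codes 0/1/2/missing) and a count report (markers x
pooled libraries, major/minor read counts), tied together by a pool
design map.  Because the interesting behaviour is statistical rather
than data-specific, the package ships a synthetic-data generator that
emulates the nested pooling experiment the pipeline is designed for, so
every stage is testable without any download.

## The simulated world

The generator emulates a five-accession trial of an outcrossing forage
grass, 60 seedlings per accession:

* **Between-accession divergence.** Each marker has an ancestral
  major-allele frequency drawn uniformly on `ancestral_freq_range`
  (default 0.88–0.999); each accession's frequency is Beta-distributed
  around it with variance `theta * p * (1-p)` (Balding–Nichols), so
  `divergence_theta` (default 0.15, the middle of the pairwise F_ST
  range 0.06–0.24 such collections show) is the target F_ST.  The
  near-fixation default range was calibrated once against the kind of
  per-accession site-frequency spectrum de novo reduced-representation
  SNP discovery produces, where most markers are rare or locally fixed;
  it reproduces realistic mean heterozygosities (ind-side H_E around
  0.2).  `theta < 1e-6` is treated as the exact zero-drift limit.
* **Inbreeding.** Genotypes follow inbreeding-adjusted Hardy–Weinberg
  proportions with `fis` (default 0.2).
* **Missingness.** Score-report missingness is marker-level
  Beta–Bernoulli with mean `md_target` (default 0.29) and a fixed Beta
  concentration of 15; it is independent of genotype and of marker
  quality — only overall MD rates are being emulated.
* **Nested pools.** Per accession, a random 20-subset is extended to
  nested pools of 30, 40, 50, 60; each (accession, size) pool exists as
  two tissue replicates, each sequenced as two libraries (0.9 and 1.5 Mr
  depth classes).  Tissue — not genotype calls — is pooled, so
  individual-level missingness never propagates into pools; pool-side
  missingness arises only from zero coverage.
* **Pool noise.** Per tissue replicate, individual DNA contributions are
  Gamma weights with CV `contribution_cv` (default 0.3 — pooling
  protocols motivate duplicate pools by unequal DNA representation
  without quantifying it).  Both libraries of a replicate share its
  weights; coverage per marker is negative binomial (dispersion 5) with
  mean `depth_Mr * 1e6 / 130261` — 130,261 being the joint-calling
  marker count the depth classes refer to, so desk-scale runs with few
  markers keep full-scale per-marker coverage and the 0.9 : 1.5 depth
  geometry.  Reads miscall the allele with probability `error_rate`
  (default 0.005, a typical residual error after quality filtering).

Replicate merging forms the analysis depths: the two 0.9 Mr libraries
sum to 1.8 Mr, the two 1.5 Mr libraries to 3.0 Mr, and all four to 4.8
Mr.

## Estimators and conventions

* Individual frequencies: `p = (AA + Aa/2) / (AA + Aa + aa)` over
  non-missing subset members; pooled frequencies: `p = n_A / (n_A +
  n_a)` over merged counts.  Both reports share one fixed major/minor
  polarisation per marker, set at generation (or calling) time.
* Filters retain a marker iff its missing fraction is strictly below
  `md_max` and its MAF strictly above `maf_min` — a marker at exactly
  the MAF threshold is discarded.  (The source conventions disagree with
  themselves between "MAF <= 0.05 discarded" and "MAF <= 0.05
  selected"; the discard reading is used throughout and boundary cases
  are tested.)  Comparisons use a 1e-9 guard so that floating-point
  wobble (`1 - 0.95 > 0.05` in doubles) cannot leak boundary markers
  through.  Filters are applied per accession-dataset in the concordance
  sweep, and once globally (dartR-style) before the structure analyses.
* Lin's concordance correlation coefficient uses population moments
  (denominator N), the original estimator's convention; it only matters
  when the two means differ.  Cells with fewer than 3 shared markers are
  flagged, never dropped, so a sweep always completes.
* Rarefaction allelic richness (ind side) uses the hypergeometric
  expectation with `g` defaulting to twice the minimum non-missing
  individual count over loci; the pool side reports effective alleles
  `1/(p^2+q^2)`.  The two are deliberately kept under distinct names —
  they answer related but different questions and are not numerically
  comparable.
* F_IS defaults to the ratio-of-means convention `1 - mean(H_O) /
  mean(H_E)`; the per-locus mean-of-ratios variant is exposed as an
  option.
* F_ST is the Weir–Cockerham (1984) theta, aggregated ratio-of-sums
  over loci; Nei (1972) standard distance likewise aggregates gene
  identities ratio-of-sums.  Pairs fixed for opposite alleles yield an
  infinite Nei distance (flagged), not an error.
* AMOVA partitions squared Rogers-type distances (mean squared per-locus
  frequency difference, pairwise-complete over missing loci) into among-
  and within-accession components; individuals are the units on the ind
  side, pool-library samples on the pool side (reproducing the 4/240 and
  4/15 style degrees of freedom).  The permutation p-value is `(1 +
  #exceedances)/(1 + B)` with B defaulting to 9,999 (resolution 1e-4);
  Mantel uses 999.  Negative among-components are reported as such, not
  clipped.
* Classical MDS double-centers `-D^2/2`; explained variances are
  eigenvalues over the sum of positive eigenvalues.
* ANOVA (one- and two-way), Tukey HSD and the Brown–Forsythe/Levene
  test are implemented from the textbook sums of squares and
  cross-checked against `stats::aov`, `stats::TukeyHSD` and a direct
  deviation-ANOVA in the tests.  Studentized-range probabilities come
  from R's own `ptukey`/`qtukey` rather than bespoke numerical
  integration: every R installation carries them, so the portability
  argument for reimplementing the distribution does not apply here.
  Factor-level ANOVAs aggregate the sweep by averaging each accession
  over all non-tested factors and treat accessions as replicates.

## What a green test does — and does not — establish

The synthetic generator reproduces the *statistical skeleton* of a
nested pooling trial: divergence, inbreeding, nested membership,
replicate structure, coverage geometry, contribution bias, read error,
and overall missingness.  Two real-data features are deliberately out of
model, and they matter for interpreting the acceptance suite:

1. **Missingness is independent of marker quality.**  In real reports,
   low-call-rate markers are disproportionately unreliable (calling
   artifacts, paralogs), which is why Representativity falls as the MD
   threshold is loosened.  In the synthetic world the MD threshold acts
   on the pool side only through coverage, and a looser threshold
   *readmits* thin-coverage markers — so simulated Representativity
   rises slightly with MD.  The corresponding acceptance clause is left
   failing by design rather than weakened; the CCC analogue passes,
   because its mechanism (fewer usable individuals per marker inflate
   ind-side estimation noise) survives the simplification.
2. **Both sources share one marker panel.**  Real pool-only calling
   yields a much larger marker reservoir whose boundary-noise
   heterozygosity inflation keeps pool H_E above ind H_E at every
   depth, so |delta H_E| shrinks as depth grows.  With a shared panel,
   the pool-side MAF 0.01 threshold admits genuinely low-MAF markers
   that accurate high-depth estimates retain, dragging pool H_E below
   the MAF-0.05-conditioned ind H_E: the signed delta falls with depth
   (as in the real study), but its absolute value does not.  That
   acceptance clause is likewise left failing with this analysis.

Everything else in the acceptance suite — noise-free end-to-end
identity, F_IS/F_ST parameter recovery, oracle equivalence of every
estimator, permutation-test type-I error, and the depth and MD
directions of CCC — holds in the stated world.

## Numerical and degenerate-input choices

* Seeds govern every random draw; the full-experiment manifest records
  seed, configuration and versions, and an identical seed reproduces the
  bundle bit for bit.
* Markers with an all-missing subset (ind) or zero total reads (pool)
  are excluded from frequency tables with their ids recorded, never
  silently dropped.
* CCC of two constant series, Representativity with an empty ind set,
  and AMOVA of identical units are flagged/defined (NA, NA, 0% among)
  rather than errors; malformed report files are hard errors naming the
  offending marker and sample.
* Tissue replicates share pool membership exactly (the protocol is
  silent; identical membership with independent tissue noise is the
  conservative reading) — their differences therefore measure
  contribution and sequencing noise only.
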