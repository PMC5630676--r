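---
title: "cfhmc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfhmc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cfhmc` analyzes paired cell-free DNA sequencing libraries: a 5hmC
*pull-down* (selective chemical labeling and streptavidin capture of
5hmC-bearing fragments) and an unenriched *input* from the same plasma
sample. This vignette documents the statistical models, the tunable
parameters and their defaults, the design decisions taken where the
methodology was genuinely open, and what the synthetic cohort generator
does and does not emulate.

## Coordinate and counting conventions

All intervals are 0-based half-open (BED convention) throughout; conversion
to 1-based closed coordinates happens only at the GenomicRanges boundary,
so touching intervals never overlap. The counting unit is the sequenced
*fragment* (a read pair extended to its template), not the read. Strand is
ignored for all counting and retained only on gene models to orient
promoters and metagene profiles. Duplicates are exact (chrom, start, end)
triples — a desk-scale proxy for positional read-pair deduplication.

## Spike-in QC

Three 180-bp amplicon controls carrying C, 5mC or 5hmC are spiked into the
cfDNA. For each control, the read fraction is
`reads / (genome-mapped reads + spike reads)` and the fold enrichment is
the pull-down fraction over the input fraction, which is invariant to
library depth. A zero input fraction yields `NA` ("undefined"), never
infinity. The pass gate (5hmC fold ≥ 20, C/5mC fold ≤ 5) is deliberately
permissive: a working pull-down shows roughly 100-fold 5hmC enrichment, but
the gate exists only to flag outright failures; the measured folds are the
evidence and are always reported.

## hMR calling

5hmC-enriched regions (hMRs) are called with a Poisson local-background
model in the spirit of MACS's default caller, re-implemented rather than
wrapped because the inputs are already full-length fragment intervals, so
model-based shift estimation would be meaningless:

- fixed 500-bp windows stepped by 100 bp (`window_bp`, `step_bp`);
  fragments enter a window through their midpoint;
- expected count `λ = max(λ_genome, λ_1kb, λ_5kb, λ_10kb) × r`, where each
  `λ_s` is the input fragment rate in a window of scale `s` centered on the
  test window, rescaled to 500 bp, and `r` is the pull-down/input depth
  ratio. Taking the maximum makes the test conservative wherever the local
  input estimate is noisy;
- a window is significant when `P(X ≥ k | λ) < 1e-5`, evaluated through the
  Poisson survival function (no `1 − CDF` cancellation; every reported
  p-value is checked against direct summation of the mass function in the
  test suite);
- overlapping or touching significant windows are merged and all statistics
  (count, λ, p, fold) are recomputed on the merged extent. Scale windows
  shorter than the merged region are widened to the region length.

hMR counts are reported per million mapped pull-down fragments so that a
global loss of enrichment (the lung-cancer-like phenotype) is visible as a
drop in normalized hMR counts. Replicate concordance is the fraction of one
set's regions overlapping the other by ≥ 1 bp.

Genomic annotation partitions the genome into exon > promoter (5 kb
upstream of the TSS) > intron > intergenic, with the priority order
resolving ambiguous assignments — the partition is then disjoint, expected
fractions are genome shares, and each hMR is assigned to the
highest-priority category it overlaps by ≥ 1 bp. The priority order is a
design choice for determinism; with peaky genic signal almost every genic
hMR touches an exon, so exon o/e is high and intergenic o/e is far below 1
by construction of the synthetic data.

## Quantification

FPKM is `count / (feature_kb × mapped_millions)`, counting a fragment once
per feature it overlaps by ≥ 1 bp (bedtools-intersect semantics; a fragment
spanning two adjacent 2-kb windows contributes to both). Gene-body
quantification excludes genes shorter than 1 kb and genes on chrX/chrY;
window quantification excludes windows overlapping the blacklist; promoter
windows truncated at chromosome edges use their actual length in the
denominator.

Metagene profiles scale each gene body to 100 bins with 40 fixed-width bins
over each 2-kb flank (our choice; profile-binning conventions vary between
tools and nothing downstream depends on them). The per-bin signal is
`log2(((pd + 0.5)/N_pd) / ((in + 0.5)/N_in))` — a symmetric 0.5-fragment
pseudocount before depth normalization, so identical libraries give exactly
zero — averaged over genes within each expression tertile (tertiles by
rank, ties broken by gene id for determinism). Minus-strand genes are
reversed.

## Differential statistics

- **Welch t** for two-group cohort contrasts: unequal-variance t with
  Welch–Satterthwaite degrees of freedom, two-tailed p. Zero variance in
  both groups with equal means gives `t = 0, p = 1`; with unequal means the
  result is flagged degenerate with `p = 0`.
- **Moderated t** for differential gene calling: per-feature residual
  variances `s²_g` (d_g df) are shrunk toward a prior `s₀²` with d₀ df
  estimated by moment matching on `log s²_g` using digamma/trigamma
  relations (the trigamma inverse is a safeguarded Newton iteration; a
  non-positive moment estimate maps to d₀ = ∞, i.e. full shrinkage). The
  posterior variance is `(d₀s₀² + d_g s²_g)/(d₀ + d_g)` and the moderated t
  has `d₀ + d_g` df. The implementation is cross-checked against limma in
  the test suite. The design is deliberately two-group only (no covariates,
  weights or variance trend): every contrast in this pipeline is two-group.
- **BH q-values** via `stats::p.adjust("BH")`, verified against a
  brute-force step-down oracle. Note that the BH transform is *not*
  idempotent (re-adjusting q-values inflates them); the suite asserts
  monotonicity in sorted-p order instead.
- **Selection thresholds**: `q < q_max` and `max(FC, 1/FC) > fc_min`, with
  fold change computed on group means offset by ε = 0.1 FPKM to stabilize
  near-zero genes (rank-preserving). A threshold of 1.41 is read as
  `|log2FC| > 0.5` (√2).

## CNV estimation

Input-library fragments are binned at 1 Mb by midpoint (one fragment, one
bin — totals are conserved); bins with coverage-weighted mean mappability
below 0.8 are excluded. GC bias is corrected with LOESS (span 0.3, degree
2, direct surface so prediction works at the GC range edges):
`corrected = count × mean(fitted)/fitted`, an identity when GC is constant.
Corrected counts are scaled so the retained-bin mean is exactly 2 (diploid
center), capped at 5 to limit extreme bins, and smoothed with a centered
20-bin moving average computed within each chromosome — truncated (not
NA-padded) at chromosome ends, skipping excluded bins. Centered rather than
trailing smoothing is our choice; the window is placed 9 bins back / 10
forward. Because scaling centers the *mean* at 2, a gained segment's scaled
level approaches its true copy number only when the diploid background
dominates the genome, which is why the CNV recovery benchmark uses a 30-Mb
gain on a 1-Gb genome.

## Classification

Feature selection follows three comparison rules — each cancer vs healthy,
each cancer vs all other cancer samples pooled (healthy excluded; the
literal reading of the rule), and every cancer pair — with a pooled-variance
Student t per feature, BH correction *within* each comparison (ranks are
per-comparison), ranking by (q, p, feature id) for determinism, and the
top 5 per comparison, deduplicated across comparisons. Selection runs on
training samples only; `loo_cross_validate()` re-selects inside every fold.
Passing a pre-computed feature set bypasses per-fold selection and is
provided exactly to demonstrate the leakage it causes: on label-permuted
null data, honest per-fold selection stays at chance while whole-cohort
selection inflates accuracy far above it. (On null data the honest
procedure actually sits slightly *below* nominal chance: the held-out
sample's class always has one fewer training sample and hence a lower
class prior — the familiar pessimistic bias of cross-validation.)

The Gaussian-mixture classifier is EDDA-style: one Gaussian component per
class, with either a shared diagonal covariance (EEI: `λ_j` = pooled
within-class variance per dimension, MLE divisor n) or per-class spherical
covariances (VII: `λ_k` = mean within-class variance over dimensions).
Variances are floored at 1e-6 against degenerate directions. The reported
log-likelihood is the classification likelihood
`Σᵢ log N(xᵢ; μ_{yᵢ}, Σ_{yᵢ})` and `BIC = 2 logL − m log n`; by default
both structures are fit and the higher-BIC one kept, resolving the EEI/VII
choice the way a BIC plot would. Prediction is posterior argmax with ties
broken by class order; posteriors use a log-sum-exp. The random-forest
classifier delegates to `randomForest` with a fixed seed (default 5) set
before every fit, so runs are reproducible; mean-decrease-Gini importances
are returned.

Cohen's κ uses marginal-product expected agreement and the
Fleiss–Cohen–Everitt asymptotic standard error for its 95% CI; κ is
undefined (NA, flagged) when both raters use a single label. Accuracy is
reported both per stage-resolved label and "type-only" with the two lung
stages collapsed.

The disease score is a Fisher discriminant between one case group and one
control group with ridge-regularized within-class scatter
(`α = 1e-3 × trace(S_w)/d`, necessary because the feature count typically
exceeds the sample count), affinely calibrated so the training control mean
scores 0 and the training case mean scores 1; held-out longitudinal samples
are scored with the frozen direction and calibration.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` plants known effects so that every stage can be tested
against ground truth:

- a 3 × 10 Mb genome with 1 200 non-overlapping genes (log-normal lengths
  ≥ 1 kb), 1-kb GC (Beta, mean 0.41) and mappability tracks (~5% of bins
  below 0.8), and ~1% blacklist;
- each gene's 5hmC mass concentrated in one fixed ~600-bp peak inside the
  body (real hydroxymethylomes are peaky — this is what makes hMRs callable
  and replicate-concordant at desk-scale depth) with the *body-average*
  enrichment equal to `base_enrichment × tertile multiplier`, defaults 25
  and 0.5/1/2, so aggregate genic/intergenic ratios recover the configured
  values exactly;
- class effects: HCC-like 300 up + 500 down genes at |log2FC| = 1
  (recurrence shares the profile, post-op reverts to healthy; HBV carries
  50 overlapping genes at half effect); pancreatic-like 350 + 350;
  lung-like global loss factors 0.6 (non-metastatic) and 0.2 (metastatic)
  multiplying all genic enrichment; chromosome-scale CNV segments (e.g. a
  copy-3 half-chromosome in metastatic lung);
- spike-ins at molar ratio 2e-3 per control with capture probabilities 0.5
  (5hmC) and 0.004 (5mC, C) against a mean genomic capture rate of 0.0015,
  giving an expected 5hmC fold enrichment near 140 with tallies stable at
  the default depth. The spike mass fraction is exaggerated relative to
  real libraries so that input tallies remain informative at 10⁵ fragments;
- exactly `depth` fragments per library (default 10⁵, cfDNA-like 180 ± 20
  bp lengths), all randomness derived from one master seed with per-sample
  streams obtained by hashing (seed, sample id) — the whole cohort is
  reproducible and individual samples are independent of cohort order;
- default class sizes 8 healthy, 7 HBV, 10 pre-op HCC (+4 post-op, +3
  recurrence), 8 + 7 lung, 7 pancreatic, so the classification subset has
  40 samples across five groups.

It does **not** emulate sequence content (no FASTQ, no alignment or
mapping errors), fragment-length biology, PCR chemistry, batch effects, age
structure, or biological within-class heterogeneity beyond sampling noise.
Passing tests therefore demonstrate that the algorithms recover planted
effects of realistic size and calibrate correctly under their stated null
models — not that any particular clinical accuracy would be attained on
real plasma cohorts, where class differences are subtler and confounders
exist.

## Problem sizes used in the validation suite

The test and acceptance suites choose deliberately compact problem sizes:
libraries of 2 × 10⁴ fragments for mechanical checks and 10⁵ for
statistical ones; peak-calling power/FDR on the 30-Mb genome with 200
planted 2-kb regions at 10× enrichment; replicate concordance via random
half-splits of one 10⁵-fragment sample; moderated-t calibration on 2 000
null features at n = 5 + 5; CNV recovery of a 30-Mb copy-3 segment on a
1-Gb diploid genome at 2 × 10⁵ fragments; classification on the default
40-sample cohort, with null-cohort integrity checks over five label
permutations of a 2 000-feature Gaussian matrix.

## Known limitations

- The peak caller is MACS-like, not MACS: no fragment-shift model, no
  mfold pre-filtering, no broad-peak mode, no FDR column.
- The moderated t has no variance trend ("limma-trend") and no multi-factor
  designs.
- CNV output is a smoothed profile, not segmentation: no breakpoints,
  allele-specific states or tumor-fraction estimates.
- The EDDA classifier fits exactly two covariance structures (EEI, VII);
  the full mclust model family is out of scope.
- BED/bedGraph/gene-model I/O is plain-text only (no BAM/bigWig); aligned,
  deduplicated fragment intervals are the expected input, and extension of
  discordant read pairs into fragments is upstream of this package.
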