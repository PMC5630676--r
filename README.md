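# cfhmc

Analysis of cell-free DNA 5-hydroxymethylcytosine (5hmC) enrichment
sequencing in R.

Circulating cell-free DNA (cfDNA) carries epigenetic marks from the tissues
that shed it. Selective chemical labeling of 5hmC (βGT-mediated glucosylation,
biotin click chemistry, streptavidin pull-down) lets the rare 5hmC-marked
fraction of cfDNA be enriched and shotgun-sequenced from nanogram inputs,
alongside an unenriched *input* library from the same plasma. `cfhmc`
implements the downstream computational stack for such paired libraries, for
anyone analyzing enrichment-based cfDNA epigenomics or building liquid-biopsy
classifiers on top of it:

- **Spike-in QC** — capture fractions and fold enrichment of C / 5mC / 5hmC
  amplicon controls (`spike_report()`); a successful pull-down shows on the
  order of 100-fold 5hmC enrichment with no enrichment of C/5mC.
- **hMR calling** — 5hmC-enriched regions from pull-down vs input with a
  MACS-style Poisson model (`call_hmrs()`): 500-bp windows stepped by 100 bp,
  local background `λ = max(λ_genome, λ_1kb, λ_5kb, λ_10kb)` estimated from
  the depth-scaled input, windows kept at `P(X ≥ k | λ) < 1e-5` and merged.
  Replicate concordance (`hmr_concordance()`) and genomic annotation with
  observed/expected category ratios (`annotate_hmrs()`).
- **Quantification** — 5hmC FPKM (fragments per kb of feature per million
  mapped fragments) over gene bodies, 5-kb promoters, or genome-wide 2-kb
  windows ("DhMR" features), plus metagene profiles of
  `log2(pulldown/input)` by expression tertile.
- **Differential hydroxymethylation** — Welch t, an empirical-Bayes
  moderated t (variance shrinkage with closed-form prior estimation on
  `log s²`), Benjamini–Hochberg q-values, and q/fold-change gene selection.
- **CNV estimation from cfDNA** — 1-Mb bins, mappability filter (< 0.8
  excluded), GC-LOESS correction, scaling to a diploid mean of 2, capping at
  5, and a 20-Mb within-chromosome moving average (`estimate_cnv()`).
- **Cancer-type classification** — per-fold feature selection (top 5 genes
  by q-value from cancer-vs-healthy, cancer-vs-other-cancers and pairwise
  comparisons), EDDA Gaussian-mixture (EEI/VII chosen by BIC) and
  random-forest classifiers under leave-one-out cross-validation, Cohen's κ
  for inter-classifier agreement, and a ridge-regularized LDA "disease
  score" calibrated so healthy = 0 and pre-treatment disease = 1
  (`loo_cross_validate()`, `cohens_kappa()`, `lda_score()`).
- **Synthetic cohort generator** — a fully synthetic genome, annotation and
  labeled cohort with planted ground truth (`simulate_cohort()`): genic 5hmC
  peaks scaled by expression tertile, disease-specific differential genes,
  stage-dependent global loss of enrichment, chromosome-scale CNV segments,
  and modification-specific spike-in capture. Every pipeline stage is
  validated against these planted effects.

## Worked example

```r
library(cfhmc)

cfg <- cohort_config(n_per_class = c(Healthy = 4, HCC_preop = 4, Lung_M = 4),
                     n_genes = 400, depth = 2e4, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <synthetic_cohort> 12 samples, 400 genes, 3 chromosome(s) x 10 Mb, depth 20000
#> HCC_preop   Healthy    Lung_M
#>         4         4         4

s <- cohort$samples$Healthy_01
print(spike_report(s$spike, s$pulldown$total_mapped, s$input$total_mapped),
      digits = 3)
#>   control modification pulldown_fraction input_fraction fold_enrichment
#> 1     hmC          hmC           0.28399        0.00189         150.426
#> 2      mC           mC           0.00231        0.00248           0.931
#> 3       C            C           0.00221        0.00199           1.110

h <- call_hmrs(s$pulldown, s$input, cohort$genome$tracks$chrom_sizes)
h
#> <hmr_set> Healthy_01: 353 regions (17650.0 per million mapped), 299988 windows tested
head(h$regions, 3)
#>   chrom  start    end count    lambda      p_value     fold
#> 1  chr1  36800  38200    62 1.0000000 1.187835e-86 62.00000
#> 2  chr1  75800  77200    47 2.0000000 7.684577e-47 23.50000
#> 3  chr1 175900 177000    17 0.7333333 7.220982e-18 23.18182

mat <- build_feature_matrix(cohort, "gene_body")
lab <- ifelse(cohort$labels$class == "HCC_preop", "HCC", cohort$labels$class)
mc <- loo_cross_validate(mat, lab, classifier = "mclust",
                         cancer_groups = c("HCC", "Lung_M"))
mc
#> <prediction_report> mclust: accuracy 0.917 (type-only 0.917), n = 12
cohens_kappa(mc$predictions$predicted, lab)$kappa
#> [1] 0.875
```

The spike report shows the hallmark of a working pull-down: the 5hmC control
is captured ~150× more efficiently than in the input, while the C and 5mC
controls sit at ~1×. The called regions land on the planted genic 5hmC peaks
(`count` ≫ `lambda`), and even this deliberately tiny cohort (4 samples per
class, 20 000 fragments per library) is classified at 11/12 with
leave-one-out cross-validation, with κ = 0.875 against the true labels.

`run_pipeline()` / `demo_pipeline()` orchestrate all stages end to end and
write provenance-stamped TSV/JSON artifacts (spike QC, hMR BED files and
summary, FPKM matrix, differential tables, CNV profiles, per-fold LOO
predictions).

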