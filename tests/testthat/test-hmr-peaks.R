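test_that("poisson_tail matches direct summation of the mass function", {
  expect_equal(poisson_tail(0, 0.5), 1)
  expect_equal(poisson_tail(0, 100), 1)
  expect_equal(poisson_tail(5, 1), bf_poisson_tail(5, 1), tolerance = 1e-12)
  # deep tail: relative agreement, no cancellation
  expect_equal(poisson_tail(50, 5) / bf_poisson_tail(50, 5), 1,
               tolerance = 1e-12)
  for (k in c(1, 3, 17, 120)) for (lam in c(0.2, 2, 40)) {
    expect_equal(poisson_tail(k, lam) / bf_poisson_tail(k, lam), 1,
                 tolerance = 1e-10)
  }
  expect_error(poisson_tail(3, 0), "lam")
  expect_error(poisson_tail(-1, 1), "integer")
})

test_that("a planted enriched region is called over most of its extent", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1), n_chroms = 1,
                       chrom_len = 5e6, n_genes = 0, depth = 2e4, seed = 8)
  g <- generate_genome(cfg)
  planted <- data.frame(chrom = "chr1", start = 2e6, end = 2e6 + 2000,
                        fold = 10)
  tr <- make_truth(g, cfg, extra_regions = planted)
  s <- simulate_sample("Healthy", "p", tr, g, cfg)
  h <- call_hmrs(s$pulldown, s$input, g$tracks$chrom_sizes)
  ov <- GenomicRanges::intersect(
    cfhmc:::as_granges0(h$regions), cfhmc:::as_granges0(planted))
  covered <- sum(IRanges::width(ov)) / 2000
  expect_gte(covered, 0.8)
  expect_true(all(h$regions$fold >= 1))
  expect_true(all(h$regions$p_value > 0 & h$regions$p_value <= 1))
})

test_that("no calls on a chromosome with an empty pulldown", {
  cs <- c(chr1 = 1e6, chr2 = 1e6)
  set.seed(3)
  pd_st <- floor(runif(2000, 0, 1e6 - 200))
  in_st <- floor(runif(2000, 0, 2e6 - 200))
  pd <- toy_fragments(rep("chr1", 2000), pd_st, pd_st + 180)
  inp <- toy_fragments(ifelse(in_st < 1e6, "chr1", "chr2"),
                       in_st %% 1e6, in_st %% 1e6 + 180, library = "input")
  h <- call_hmrs(pd, inp, cs)
  expect_false("chr2" %in% h$regions$chrom)
  empty <- toy_fragments(character(0), numeric(0), numeric(0))
  expect_error(call_hmrs(empty, inp, cs), "zero-depth")
})

test_that("calls are stable under exact depth doubling of both libraries", {
  co <- small_cohort()
  s <- co$samples[["Healthy_01"]]
  cs <- co$genome$tracks$chrom_sizes
  h1 <- call_hmrs(s$pulldown, s$input, cs)
  dbl <- function(f) fragment_set(f$sample_id, f$library,
                                  rbind(f$fragments, f$fragments))
  h2 <- call_hmrs(dbl(s$pulldown), dbl(s$input), cs)
  # doubling counts and lambdas only sharpens p-values: originals stay called
  expect_gte(hmr_concordance(h1, h2), 0.95)
})

test_that("merged regions are disjoint and merging is idempotent", {
  co <- small_cohort()
  s <- co$samples[["HCC_preop_01"]]
  h <- call_hmrs(s$pulldown, s$input, co$genome$tracks$chrom_sizes)
  r <- h$regions
  expect_gt(nrow(r), 10)
  merged <- reduce_intervals(r)
  expect_equal(nrow(merged), nrow(r))
  # region p-values match the brute-force tail on (count, lambda)
  idx <- head(order(r$p_value), 25)
  for (i in idx)
    expect_equal(r$p_value[i] / bf_poisson_tail(r$count[i], r$lambda[i]), 1,
                 tolerance = 1e-10)
})

test_that("hmr concordance handles identity and disjoint sets", {
  a <- genomic_intervals(rep("chr1", 3), c(0, 1000, 5000),
                         c(500, 1500, 5600))
  b <- genomic_intervals("chr1", 10000, 11000)
  expect_equal(hmr_concordance(a, a), 1)
  expect_equal(hmr_concordance(a, b), 0)
})

test_that("uniformly placed regions have o/e near 1 in every category", {
  co <- small_cohort()
  g <- co$genome
  set.seed(31)
  n <- 2000
  ch <- sample(names(g$tracks$chrom_sizes), n, TRUE)
  st <- floor(runif(n, 0, g$tracks$chrom_sizes[ch] - 1000))
  unif <- genomic_intervals(ch, st, st + 1000)
  ann <- annotate_hmrs(unif, g$genes, g$tracks$chrom_sizes)
  # categories are a partition: expected fractions sum to 1
  expect_equal(sum(ann$expected_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ann$observed_fraction), 1, tolerance = 1e-9)
  # a 1-kb query can graze a rare category, inflating small-category o/e;
  # intergenic dominates and must be near 1
  inter <- ann[ann$category == "intergenic", ]
  expect_equal(inter$o_over_e, 1, tolerance = 0.15)
  expect_error(annotate_hmrs(unif[0, ], g$genes, g$tracks$chrom_sizes),
               "empty")
})

test_that("hMRs called on synthetic samples are overwhelmingly genic", {
  co <- small_cohort()
  s <- co$samples[["Healthy_02"]]
  h <- call_hmrs(s$pulldown, s$input, co$genome$tracks$chrom_sizes)
  ann <- annotate_hmrs(h, co$genome$genes, co$genome$tracks$chrom_sizes)
  intragenic <- sum(ann$observed_fraction[ann$category != "intergenic"])
  expect_gte(intragenic, 0.7)
  expect_lt(ann$o_over_e[ann$category == "intergenic"], 1)
  # all hMRs inside exons degenerates to exon fraction 1
  ex <- gene_exons(co$genome$genes)[1:20, c("chrom", "start", "end")]
  ann2 <- annotate_hmrs(ex, co$genome$genes, co$genome$tracks$chrom_sizes)
  expect_equal(ann2$observed_fraction[ann2$category == "exon"], 1)
})
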