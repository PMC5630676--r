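test_that("genome and samples are deterministic given the seed", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1), n_genes = 100,
                       depth = 5000, seed = 9)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$tracks$gc$value, g2$tracks$gc$value)

  tr <- make_truth(g1, cfg)
  s1 <- simulate_sample("Healthy", "a", tr, g1, cfg)
  s2 <- simulate_sample("Healthy", "a", tr, g1, cfg)
  expect_identical(s1$pulldown$fragments, s2$pulldown$fragments)
  expect_identical(s1$spike, s2$spike)
  # a different sample id gives a different draw
  s3 <- simulate_sample("Healthy", "b", tr, g1, cfg)
  expect_false(identical(s1$pulldown$fragments, s3$pulldown$fragments))
  expect_error(simulate_sample("NotAClass", "x", tr, g1, cfg),
               "unknown class")
})

test_that("zero genes yields valid tracks and an empty gene set", {
  cfg <- cohort_config(n_genes = 0, n_chroms = 1, chrom_len = 1e6, seed = 4)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  expect_equal(sum(g$tracks$chrom_sizes), 1e6)
  expect_true(all(g$tracks$gc$value > 0 & g$tracks$gc$value < 1))
})

test_that("about 5% of mappability bins fall below 0.8", {
  g <- generate_genome(cohort_config(seed = 21))   # 30k 1-kb bins
  frac <- mean(g$tracks$mappability$value < 0.8)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_true(all(g$tracks$mappability$value <= 1))
})

test_that("library depth is exact and blacklist covers about 1%", {
  co <- small_cohort()
  for (s in co$samples[1:2]) {
    expect_equal(s$pulldown$total_mapped, co$config$depth)
    expect_equal(s$input$total_mapped, co$config$depth)
  }
  bl <- co$genome$tracks$blacklist
  expect_equal(sum(bl$end - bl$start) / sum(co$genome$tracks$chrom_sizes),
               0.01, tolerance = 0.5)
})

test_that("input counts recover the planted copy-number ratio", {
  cfg <- cohort_config(n_per_class = c(Lung_M = 1), n_genes = 200,
                       depth = 1e5, seed = 13)
  g <- generate_genome(cfg)
  tr <- make_truth(g, cfg)
  s <- simulate_sample("Lung_M", "cn", tr, g, cfg)
  seg <- tr$cnv$Lung_M        # chr3 first half at copy 3
  fr <- s$input$fragments
  mid <- floor((fr$start + fr$end) / 2)
  gain <- fr$chrom == seg$chrom & mid >= seg$start & mid < seg$end
  base <- fr$chrom == seg$chrom & mid >= seg$end
  ratio <- (sum(gain) / (seg$end - seg$start)) /
    (sum(base) / (g$tracks$chrom_sizes[[seg$chrom]] - seg$end))
  expect_equal(ratio, 1.5, tolerance = 0.05)
})

test_that("pull-down genic enrichment matches the configured baseline", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1),
                       tertile_mult = c(low = 1, mid = 1, high = 1),
                       depth = 2e5, seed = 5)
  g <- generate_genome(cfg)
  tr <- make_truth(g, cfg)
  s <- simulate_sample("Healthy", "x", tr, g, cfg)
  gb <- g$genes[, c("chrom", "start", "end")]
  fr <- s$pulldown$fragments
  mid <- floor((fr$start + fr$end) / 2)
  mids <- data.frame(chrom = fr$chrom, start = mid, end = mid + 1)
  ng <- sum(count_interval_overlaps(gb, mids))
  genic_bp <- sum(gb$end - gb$start)
  tot_bp <- sum(g$tracks$chrom_sizes)
  ratio <- (ng / genic_bp) /
    ((s$pulldown$total_mapped - ng) / (tot_bp - genic_bp))
  expect_equal(ratio, cfg$base_enrichment, tolerance = 0.05)
})

test_that("global loss factor scales genic enrichment between classes", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1, Lung_M = 1),
                       tertile_mult = c(low = 1, mid = 1, high = 1),
                       depth = 2e5, seed = 6)
  g <- generate_genome(cfg)
  tr <- make_truth(g, cfg)
  enr <- function(class, id) {
    s <- simulate_sample(class, id, tr, g, cfg)
    fr <- s$pulldown$fragments
    mid <- floor((fr$start + fr$end) / 2)
    mids <- data.frame(chrom = fr$chrom, start = mid, end = mid + 1)
    gb <- g$genes[, c("chrom", "start", "end")]
    ng <- sum(count_interval_overlaps(gb, mids))
    genic_bp <- sum(gb$end - gb$start)
    tot_bp <- sum(g$tracks$chrom_sizes)
    (ng / genic_bp) / ((s$pulldown$total_mapped - ng) / (tot_bp - genic_bp))
  }
  r <- enr("Lung_M", "m") / enr("Healthy", "h")
  expect_equal(r, tr$loss_factor[["Lung_M"]], tolerance = 0.05)
})

test_that("planted differential effects are recovered from pulldown FPKM", {
  cfg <- cohort_config(n_per_class = c(Healthy = 6, HCC_preop = 6),
                       depth = 1e5, seed = 17)
  co <- simulate_cohort(cfg)
  mat <- build_feature_matrix(co, "gene_body")
  lab <- co$labels$class
  hcc <- co$truth$profiles$HCC
  mh <- rowMeans(mat[, lab == "Healthy"])
  mc <- rowMeans(mat[, lab == "HCC_preop"])
  fc <- log2((mc + 0.1) / (mh + 0.1))
  m <- match(hcc$gene_id, rownames(mat))
  err <- abs(fc[m] - hcc$log2fc)
  err <- err[!is.na(err)]
  expect_lt(mean(err), 0.3)          # parameter recovery on average
  expect_gt(mean(err <= 0.3), 0.85)  # and for the bulk of planted genes
})
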