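test_that("gene FPKM equals brute-force counts with filters applied", {
  co <- small_cohort()
  g <- head(co$genome$genes, 50)
  s <- co$samples[[1]]
  set.seed(19)
  idx <- sample.int(s$pulldown$total_mapped, 1000)
  f <- fragment_set("sub", "pulldown", s$pulldown$fragments[idx, ])
  q <- gene_fpkm(f, g)
  bf <- bf_overlap_counts(g[, c("chrom", "start", "end")], f$fragments)
  keep <- g$length_bp >= 1000
  expect_equal(q$count, bf[keep])
  expect_equal(q$fpkm,
               bf[keep] / (g$length_bp[keep] / 1e3 * f$total_mapped / 1e6))

  # 900-bp and chrX genes are absent
  gx <- rbind(g, data.frame(gene_id = c("short", "sexchrom"),
                            chrom = c("chr1", "chrX"),
                            start = c(0, 0), end = c(900, 5000),
                            strand = "+", exon_starts = c("0", "0"),
                            exon_ends = c("900", "5000"),
                            length_bp = c(900, 5000),
                            peak_start = c(0, 0), peak_end = c(600, 600)))
  q2 <- gene_fpkm(f, gx)
  expect_false(any(c("short", "sexchrom") %in% q2$feature_id))
})

test_that("promoter geometry is strand aware and edge truncated", {
  cs <- c(chr1 = 1e6)
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chrom = "chr1", start = c(10000, 10000, 1000),
                      end = c(20000, 20000, 8000),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  f <- toy_fragments(rep("chr1", 2), c(6000, 21000), c(6200, 21200))
  q <- promoter_fpkm(f, genes, cs)
  expect_equal(q$count[q$feature_id == "plus"], 1)   # [5000,10000) hit
  expect_equal(q$count[q$feature_id == "minus"], 1)  # [20000,25000) hit
  edge <- q[q$feature_id == "edge", ]
  expect_equal(edge$length_bp, 1000)                 # truncated at 0
  expect_equal(edge$fpkm, edge$count / (1 * f$total_mapped / 1e6))
})

test_that("window counts conserve per-fragment multiplicity; blacklist removed", {
  co <- small_cohort()
  s <- co$samples[[2]]
  set.seed(23)
  idx <- sample.int(s$pulldown$total_mapped, 2000)
  f <- fragment_set("sub", "pulldown", s$pulldown$fragments[idx, ])
  tracks <- co$genome$tracks
  w <- window_fpkm(f, tracks, window_bp = 2000)
  # conservation against the brute-force overlap multiplicity
  win_all <- tile_windows(tracks$chrom_sizes, 2000)
  bl <- count_interval_overlaps(win_all, tracks$blacklist) > 0
  mult <- bf_overlap_counts(win_all[!bl, c("chrom", "start", "end")],
                            f$fragments)
  expect_equal(w$count, mult)
  expect_equal(sum(w$count), sum(mult))
  # every blacklisted window is absent
  expect_false(any(win_all$feature_id[bl] %in% w$feature_id))
  # FPKM formula at 2 kb
  expect_equal(w$fpkm, w$count / ((w$end - w$start) / 1e3 *
                                    f$total_mapped / 1e6))
})

test_that("FPKM is exactly invariant to count scaling, stable to resampling", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1), n_genes = 400,
                       depth = 1e5, seed = 91)
  g <- generate_genome(cfg)
  tr <- make_truth(g, cfg)
  s <- simulate_sample("Healthy", "a", tr, g, cfg)
  q1 <- gene_fpkm(s$pulldown, g$genes)
  dbl <- fragment_set("d", "pulldown",
                      rbind(s$pulldown$fragments, s$pulldown$fragments))
  expect_equal(gene_fpkm(dbl, g$genes)$fpkm, q1$fpkm)
  set.seed(5)
  idx <- sample.int(s$pulldown$total_mapped, s$pulldown$total_mapped / 2)
  half <- fragment_set("h", "pulldown", s$pulldown$fragments[idx, ])
  q2 <- gene_fpkm(half, g$genes)
  expect_gt(cor(q1$fpkm, q2$fpkm), 0.95)
  expect_lt(abs(mean(q2$fpkm / pmax(q1$fpkm, 1)) - 1), 0.05)

  # technical replicates of the same subject at full depth
  r2 <- simulate_sample("Healthy", "b", tr, g, cfg)
  expect_gt(cor(q1$fpkm, gene_fpkm(r2$pulldown, g$genes)$fpkm), 0.9)
})

test_that("metagene profile is zero for pulldown == input and flips with strand", {
  co <- small_cohort()
  g <- head(co$genome$genes, 60)
  s <- co$samples[[1]]
  cs <- co$genome$tracks$chrom_sizes
  expr <- setNames(co$truth$expression$rpkm, co$truth$expression$gene_id)
  same <- metagene(s$pulldown, s$pulldown, g, expr, cs)
  expect_true(all(abs(same$value) < 1e-12))

  prof <- metagene(s$pulldown, s$input, g, expr, cs)
  gf <- g
  gf$strand <- ifelse(g$strand == "+", "-", "+")
  prof_f <- metagene(s$pulldown, s$input, gf, expr, cs)
  nb <- max(prof$bin)
  for (tt in c("low", "high")) {
    a <- prof$value[prof$tertile == tt]
    b <- prof_f$value[prof_f$tertile == tt]
    expect_equal(a, rev(b))
  }
})

test_that("flat planted enrichment shows up as ~2 log2 units over flanks", {
  cfg <- cohort_config(n_per_class = c(Healthy = 1), n_chroms = 1,
                       chrom_len = 8e6, n_genes = 60, depth = 2e5,
                       base_enrichment = 1,
                       tertile_mult = c(low = 1, mid = 1, high = 1),
                       seed = 27)
  g <- generate_genome(cfg)
  flat4 <- g$genes[, c("chrom", "start", "end")]
  flat4$fold <- 4
  tr <- make_truth(g, cfg, extra_regions = flat4)
  s <- simulate_sample("Healthy", "m", tr, g, cfg)
  expr <- setNames(rep(1, nrow(g$genes)), g$genes$gene_id)
  prof <- metagene(s$pulldown, s$input, g$genes, expr,
                   g$tracks$chrom_sizes)
  body <- mean(prof$value[prof$zone == "body"])
  flank_outer <- mean(prof$value[prof$zone != "body" &
                                   (prof$bin <= 20 | prof$bin > 160)])
  expect_equal(body - flank_outer, 2, tolerance = 0.35)
})

test_that("gene-body enrichment ranks expression tertiles high > mid > low", {
  co <- small_cohort()
  s <- co$samples[["Healthy_01"]]
  prof <- metagene(s$pulldown, s$input, co$genome$genes,
                   co$truth$expression, co$genome$tracks$chrom_sizes)
  mb <- vapply(c("low", "mid", "high"), function(tt)
    mean(prof$value[prof$tertile == tt & prof$zone == "body"]), 0)
  expect_true(mb[["high"]] > mb[["mid"]])
  expect_true(mb[["mid"]] > mb[["low"]])
})
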