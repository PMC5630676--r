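# Fragment sets -> analysis-ready features. FPKM here is fragments per
# kilobase of feature per million mapped fragments; a fragment is counted
# once per feature it overlaps by >= 1 bp (bedtools-intersect semantics), so
# a fragment spanning two adjacent windows contributes to both.

.fpkm <- function(counts, length_bp, total_mapped) {
  counts / (length_bp / 1e3 * total_mapped / 1e6)
}

#' Gene-body 5hmC FPKM
#'
#' Counts fragments overlapping each gene body (>= 1 bp) and normalizes by
#' gene length and library depth. Genes shorter than `min_len` or on the
#' chromosomes in `exclude_chroms` are excluded from the output entirely.
#'
#' @param f A [fragment_set()].
#' @param genes Gene model `data.frame`.
#' @param min_len Minimum gene-body length in bp (default 1000).
#' @param exclude_chroms Chromosomes whose genes are dropped (sex
#'   chromosomes by default).
#' @return Data frame with `feature_id`, `count`, `length_bp`, `fpkm`.
#' @export
gene_fpkm <- function(f, genes, min_len = 1000,
                      exclude_chroms = c("chrX", "chrY")) {
  stopifnot(inherits(f, "fragment_set"), f$total_mapped > 0)
  if (nrow(genes) == 0) stop("empty gene set")
  keep <- genes$end - genes$start >= min_len &
    !(genes$chrom %in% exclude_chroms)
  g <- genes[keep, , drop = FALSE]
  cnt <- count_interval_overlaps(g[, c("chrom", "start", "end")], f$fragments)
  data.frame(feature_id = g$gene_id, count = cnt,
             length_bp = g$end - g$start,
             fpkm = .fpkm(cnt, g$end - g$start, f$total_mapped),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Promoter 5hmC FPKM
#'
#' The promoter is the `upstream_bp` region upstream of the TSS (strand
#' aware: `[TSS - u, TSS)` on `+`, `[TES, TES + u)` on `-`), truncated at
#' chromosome edges; the truncated length enters the FPKM denominator.
#'
#' @param f A [fragment_set()].
#' @param genes Gene model `data.frame` with known strands.
#' @param chrom_sizes Named chromosome lengths (for edge truncation).
#' @param upstream_bp Promoter extent (default 5000).
#' @inheritParams gene_fpkm
#' @return Data frame with `feature_id`, `count`, `length_bp`, `fpkm`.
#' @export
promoter_fpkm <- function(f, genes, chrom_sizes, upstream_bp = 5000,
                          exclude_chroms = c("chrX", "chrY")) {
  stopifnot(inherits(f, "fragment_set"), f$total_mapped > 0)
  g <- genes[!(genes$chrom %in% exclude_chroms), , drop = FALSE]
  minus <- g$strand == "-"
  ps <- ifelse(minus, g$end, pmax(0, g$start - upstream_bp))
  pe <- ifelse(minus, pmin(g$end + upstream_bp, chrom_sizes[g$chrom]),
               g$start)
  keep <- pe > ps
  g <- g[keep, , drop = FALSE]; ps <- ps[keep]; pe <- pe[keep]
  cnt <- count_interval_overlaps(
    data.frame(chrom = g$chrom, start = ps, end = pe), f$fragments)
  data.frame(feature_id = g$gene_id, count = cnt, length_bp = pe - ps,
             fpkm = .fpkm(cnt, pe - ps, f$total_mapped),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tile a genome into fixed windows
#' @param chrom_sizes Named chromosome lengths.
#' @param window_bp Window size (last window per chromosome is truncated).
#' @return Sorted interval `data.frame` with a `feature_id` column
#'   (`chrom:start-end`).
#' @export
tile_windows <- function(chrom_sizes, window_bp) {
  out <- lapply(names(chrom_sizes), function(ch) {
    st <- seq(0, chrom_sizes[[ch]] - 1, by = window_bp)
    data.frame(chrom = ch, start = st,
               end = pmin(st + window_bp, chrom_sizes[[ch]]))
  })
  df <- do.call(rbind, out)
  df$feature_id <- sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
                           as.integer(df$end))
  sort_intervals(df)
}

#' Genome-window 5hmC FPKM (DhMR features)
#'
#' Tiles the genome into `window_bp` windows, removes windows overlapping
#' the blacklist (>= 1 bp), and computes FPKM per window with the actual
#' (possibly truncated) window length.
#'
#' @param f A [fragment_set()].
#' @param tracks A `genome_tracks` object (`chrom_sizes` + `blacklist`).
#' @param window_bp Window size (default 2000).
#' @return Data frame with `feature_id`, `chrom`, `start`, `end`, `count`,
#'   `fpkm`.
#' @export
window_fpkm <- function(f, tracks, window_bp = 2000) {
  stopifnot(inherits(f, "fragment_set"), f$total_mapped > 0)
  win <- tile_windows(tracks$chrom_sizes, window_bp)
  if (!is.null(tracks$blacklist) && nrow(tracks$blacklist)) {
    bl <- count_interval_overlaps(win, tracks$blacklist) > 0
    win <- win[!bl, , drop = FALSE]
  }
  cnt <- count_interval_overlaps(win, f$fragments)
  data.frame(feature_id = win$feature_id, chrom = win$chrom,
             start = win$start, end = win$end, count = cnt,
             fpkm = .fpkm(cnt, win$end - win$start, f$total_mapped),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a samples-by-features FPKM matrix from a cohort
#'
#' @param cohort A [simulate_cohort()] result (or any list of samples with
#'   `pulldown`/`input` fragment sets).
#' @param kind Feature kind: `"gene_body"`, `"promoter"` or `"window2kb"`.
#' @param library Which library to quantify.
#' @param window_bp Window size for `kind = "window2kb"`.
#' @return Numeric matrix, features x samples, with attribute
#'   `feature_kind`.
#' @export
build_feature_matrix <- function(cohort, kind = c("gene_body", "promoter",
                                                  "window2kb"),
                                 library = c("pulldown", "input"),
                                 window_bp = 2000) {
  kind <- match.arg(kind)
  library <- match.arg(library)
  tracks <- cohort$genome$tracks
  genes <- cohort$genome$genes
  cols <- lapply(cohort$samples, function(s) {
    f <- s[[library]]
    q <- switch(kind,
                gene_body = gene_fpkm(f, genes),
                promoter = promoter_fpkm(f, genes, tracks$chrom_sizes),
                window2kb = window_fpkm(f, tracks, window_bp))
    setNames(q$fpkm, q$feature_id)
  })
  ids <- names(cols[[1]])
  mat <- vapply(cols, function(x) x[ids], numeric(length(ids)))
  rownames(mat) <- ids
  colnames(mat) <- vapply(cohort$samples, `[[`, "", "sample_id")
  attr(mat, "feature_kind") <- kind
  mat
}

#' Metagene enrichment profile by expression tertile
#'
#' Each gene body is scaled to `n_body_bins` bins with `n_flank_bins`
#' fixed-width bins over each `flank_bp` flank. The per-bin signal is
#' `log2((pulldown count + 0.5) / depth_p / ((input count + 0.5) / depth_i))`
#' (0.5-fragment pseudocount before depth normalization), averaged over the
#' genes of each expression tertile. Minus-strand genes are reversed so bin 1
#' is always the upstream flank end.
#'
#' @param pulldown,input [fragment_set()]s.
#' @param genes Gene model `data.frame`.
#' @param expression Named numeric vector (or data frame with `gene_id`,
#'   `rpkm`) of expression values; tertiles are taken by rank with ties
#'   broken by gene id.
#' @param chrom_sizes Named chromosome lengths.
#' @param flank_bp Flank width (default 2000).
#' @param n_body_bins,n_flank_bins Bin counts (defaults 100 and 40).
#' @return Data frame `tertile`, `bin`, `zone` (upstream/body/downstream),
#'   `value` (mean log2 ratio).
#' @export
metagene <- function(pulldown, input, genes, expression, chrom_sizes,
                     flank_bp = 2000, n_body_bins = 100, n_flank_bins = 40) {
  if (is.data.frame(expression))
    expression <- setNames(expression$rpkm, expression$gene_id)
  g <- genes[genes$gene_id %in% names(expression), , drop = FALSE]
  if (nrow(g) < 3) stop("expression needed for at least 3 genes")
  expr <- expression[g$gene_id]
  o <- order(expr, g$gene_id, method = "radix")
  n <- nrow(g); third <- n %/% 3
  tert <- rep("mid", n)
  tert[o[seq_len(third)]] <- "low"
  tert[o[seq.int(n - third + 1, n)]] <- "high"

  nb <- 2 * n_flank_bins + n_body_bins
  fw <- flank_bp / n_flank_bins
  # bin boundaries per gene, left flank -> body -> right flank
  bounds <- t(vapply(seq_len(n), function(i) {
    c(g$start[i] - flank_bp + fw * (0:n_flank_bins),
      g$start[i] + (g$end[i] - g$start[i]) / n_body_bins * (1:(n_body_bins - 1)),
      g$end[i] + fw * (0:n_flank_bins))
  }, numeric(nb + 1)))
  len <- chrom_sizes[g$chrom]
  starts <- pmax(pmin(bounds[, -(nb + 1), drop = FALSE], len), 0)
  ends <- pmax(pmin(bounds[, -1, drop = FALSE], len), 0)
  bins <- data.frame(chrom = rep(g$chrom, nb),
                     start = floor(as.vector(starts)),
                     end = ceiling(as.vector(ends)))
  ok <- bins$end > bins$start
  cnt_one <- function(f) {
    v <- numeric(nrow(bins))
    v[ok] <- count_interval_overlaps(bins[ok, , drop = FALSE], f$fragments)
    matrix(v, nrow = n)
  }
  pd <- cnt_one(pulldown)
  ip <- cnt_one(input)
  val <- log2(((pd + 0.5) / pulldown$total_mapped) /
                ((ip + 0.5) / input$total_mapped))
  minus <- g$strand == "-"
  val[minus, ] <- val[minus, nb:1, drop = FALSE]
  zone <- rep(c("upstream", "body", "downstream"),
              c(n_flank_bins, n_body_bins, n_flank_bins))
  out <- lapply(c("low", "mid", "high"), function(tt) {
    data.frame(tertile = tt, bin = seq_len(nb), zone = zone,
               value = colMeans(val[tert == tt, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
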