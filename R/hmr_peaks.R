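# Poisson local-background calling of 5hmC-enriched regions (hMRs) from a
# pull-down library against its unenriched input, in the spirit of MACS's
# default peak caller: fixed sliding windows, a local lambda taken as the
# maximum of the genome-wide input rate and input rates in 1/5/10-kb windows,
# and merging of overlapping significant windows. No fragment-shift model is
# estimated -- the inputs are already full-length fragment intervals.

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, evaluated through the stable survival
#' function (`ppois(k - 1, lam, lower.tail = FALSE)`), so tiny tail
#' probabilities do not suffer 1-minus-CDF cancellation.
#'
#' @param k Non-negative integer count(s).
#' @param lam Positive Poisson mean(s).
#' @return `P(X >= k)` in (0, 1].
#' @export
poisson_tail <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  ppois(k - 1, lam, lower.tail = FALSE)
}

# midpoint counts of fragments in fixed-width bins along one chromosome
.bin_midpoints <- function(frags, chrom, bin_bp, chrom_len) {
  nb <- ceiling(chrom_len / bin_bp)
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  if (nrow(f) == 0) return(integer(nb))
  mid <- floor((f$start + f$end) / 2)
  tabulate(pmin(floor(mid / bin_bp) + 1, nb), nbins = nb)
}

#' Call 5hmC-enriched regions
#'
#' Scans each chromosome in sliding windows (default 500 bp, step 100 bp) of
#' pull-down fragment-midpoint counts. The expected count per window is
#' `lambda = max(genome-wide input rate, input rate in 1/5/10-kb centered
#' windows) * window / scale * (pulldown depth / input depth)`; windows with
#' `poisson_tail(count, lambda) < p_cutoff` are kept, overlapping or touching
#' significant windows are merged, and per-region statistics are recomputed
#' on the merged extent.
#'
#' @param pulldown,input [fragment_set()]s (pull-down and unenriched input).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_bp,step_bp Window and step size; `window_bp` must be a
#'   multiple of `step_bp`.
#' @param p_cutoff Poisson tail cutoff (default 1e-5).
#' @param local_scales Centered input windows (bp) entering the local lambda.
#' @return An `hmr_set`: list with `regions` (chrom, start, end, count,
#'   lambda, p_value, fold), `sample_id`, `n_per_million` (regions per
#'   million mapped pull-down fragments), `n_windows_tested`, and
#'   `windows` (the significant windows before merging).
#' @export
call_hmrs <- function(pulldown, input, chrom_sizes, window_bp = 500,
                      step_bp = 100, p_cutoff = 1e-5,
                      local_scales = c(1000, 5000, 10000)) {
  stopifnot(inherits(pulldown, "fragment_set"), inherits(input, "fragment_set"))
  if (pulldown$total_mapped == 0 || input$total_mapped == 0)
    stop("zero-depth library")
  if (window_bp %% step_bp != 0) stop("window_bp must be a multiple of step_bp")
  w <- window_bp %/% step_bp
  genome_len <- sum(chrom_sizes)
  ratio <- pulldown$total_mapped / input$total_mapped
  bg_rate <- input$total_mapped / genome_len   # input fragments per bp

  regions <- list(); sig_windows <- list(); n_tested <- 0L
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    nb <- ceiling(len / step_bp)
    if (nb < w) next
    pd <- .bin_midpoints(pulldown$fragments, ch, step_bp, len)
    ip <- .bin_midpoints(input$fragments, ch, step_bp, len)
    Cp <- c(0, cumsum(pd)); Ci <- c(0, cumsum(ip))
    nwin <- nb - w + 1L
    i <- seq_len(nwin)
    cnt <- Cp[i + w] - Cp[i]
    lam_in <- rep(bg_rate * window_bp, nwin)
    ci <- i + (w %/% 2)                         # center bin of each window
    for (s in local_scales) {
      ns <- max(1L, round(s / step_bp))
      lo <- pmax(ci - (ns %/% 2), 1L)
      hi <- pmin(ci + ((ns + 1L) %/% 2) - 1L, nb)
      covered <- (hi - lo + 1L) * step_bp
      lam_in <- pmax(lam_in, (Ci[hi + 1L] - Ci[lo]) / covered * window_bp)
    }
    lam <- lam_in * ratio
    pv <- poisson_tail(cnt, lam)
    n_tested <- n_tested + nwin
    sig <- which(pv < p_cutoff & cnt > lam)
    if (!length(sig)) next
    ws <- (sig - 1L) * step_bp
    we <- pmin(ws + window_bp, len)
    sig_windows[[ch]] <- data.frame(chrom = ch, start = ws, end = we,
                                    count = cnt[sig], lambda = lam[sig],
                                    p_value = pv[sig])
    merged <- reduce_intervals(data.frame(chrom = ch, start = ws, end = we))
    # region stats on the merged extents (boundaries are step-aligned)
    rs <- merged$start; re <- merged$end
    rcnt <- Cp[pmin(ceiling(re / step_bp), nb) + 1L] - Cp[rs %/% step_bp + 1L]
    rlen <- re - rs
    rci <- (rs + re) / 2
    rlam_in <- bg_rate * rlen
    for (s in local_scales) {
      s_eff <- pmax(s, rlen)
      lo <- pmax(floor((rci - s_eff / 2) / step_bp), 0)
      hi <- pmin(ceiling((rci + s_eff / 2) / step_bp), nb)
      covered <- (hi - lo) * step_bp
      rlam_in <- pmax(rlam_in, (Ci[hi + 1L] - Ci[lo + 1L]) / covered * rlen)
    }
    rlam <- rlam_in * ratio
    regions[[ch]] <- data.frame(chrom = ch, start = rs, end = re,
                                count = rcnt, lambda = rlam,
                                p_value = poisson_tail(rcnt, rlam),
                                fold = rcnt / rlam)
  }
  regions <- if (length(regions)) {
    out <- do.call(rbind, regions); rownames(out) <- NULL; out
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               count = numeric(0), lambda = numeric(0), p_value = numeric(0),
               fold = numeric(0))
  }
  windows <- if (length(sig_windows)) {
    out <- do.call(rbind, sig_windows); rownames(out) <- NULL; out
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               count = numeric(0), lambda = numeric(0), p_value = numeric(0))
  }
  structure(list(regions = sort_intervals(regions), windows = windows,
                 sample_id = pulldown$sample_id,
                 n_per_million = nrow(regions) * 1e6 / pulldown$total_mapped,
                 n_windows_tested = n_tested,
                 params = list(window_bp = window_bp, step_bp = step_bp,
                               p_cutoff = p_cutoff,
                               local_scales = local_scales)),
            class = "hmr_set")
}

#' @export
print.hmr_set <- function(x, ...) {
  cat(sprintf("<hmr_set> %s: %d regions (%.1f per million mapped), %d windows tested\n",
              x$sample_id, nrow(x$regions), x$n_per_million,
              x$n_windows_tested))
  invisible(x)
}

#' Replicate concordance of hMR sets
#'
#' Fraction of the regions in `a` that overlap (>= 1 bp) a region in `b`.
#' @param a,b `hmr_set` objects or interval data frames.
#' @return Fraction in \[0, 1\] (`NaN` when `a` is empty).
#' @export
hmr_concordance <- function(a, b) {
  ra <- if (inherits(a, "hmr_set")) a$regions else a
  rb <- if (inherits(b, "hmr_set")) b$regions else b
  if (nrow(ra) == 0) return(NaN)
  mean(count_interval_overlaps(ra, rb) > 0)
}

#' Genomic annotation of hMRs
#'
#' Partitions the genome into exon > promoter > intron > intergenic (priority
#' resolves overlaps, so the categories are disjoint) and assigns each hMR to
#' the highest-priority category it overlaps by >= 1 bp. Expected fractions
#' are the categories' shares of genome length.
#'
#' @param h An `hmr_set` or interval data frame (must be non-empty).
#' @param genes Gene model `data.frame`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param promoter_bp Upstream promoter extent from the TSS (default 5000).
#' @return Data frame with `category`, `observed_fraction`,
#'   `expected_fraction` and `o_over_e`.
#' @export
annotate_hmrs <- function(h, genes, chrom_sizes, promoter_bp = 5000) {
  regions <- if (inherits(h, "hmr_set")) h$regions else h
  if (nrow(regions) == 0) stop("empty hMR set")
  genome_len <- sum(chrom_sizes)
  whole <- genomic_intervals(names(chrom_sizes), 0, unname(chrom_sizes))

  exon <- if (nrow(genes)) reduce_intervals(gene_exons(genes)) else
    whole[0, c("chrom", "start", "end")]
  prom <- if (nrow(genes)) {
    tss_minus <- genes$strand == "-"
    ps <- ifelse(tss_minus, genes$end, pmax(0, genes$start - promoter_bp))
    pe <- ifelse(tss_minus,
                 pmin(genes$end + promoter_bp, chrom_sizes[genes$chrom]),
                 genes$start)
    keep <- pe > ps
    reduce_intervals(data.frame(chrom = genes$chrom[keep], start = ps[keep],
                                end = pe[keep]))
  } else whole[0, c("chrom", "start", "end")]
  body <- if (nrow(genes))
    reduce_intervals(genes[, c("chrom", "start", "end")]) else
      whole[0, c("chrom", "start", "end")]

  gr <- function(df) as_granges0(df)
  exon_gr <- gr(exon)
  prom_gr <- GenomicRanges::setdiff(gr(prom), exon_gr)
  intron_gr <- GenomicRanges::setdiff(GenomicRanges::setdiff(gr(body), exon_gr),
                                      prom_gr)
  genic_all <- GenomicRanges::union(GenomicRanges::union(exon_gr, prom_gr),
                                    intron_gr)
  inter_gr <- GenomicRanges::setdiff(gr(whole), genic_all)

  cat_grs <- list(exon = exon_gr, promoter = prom_gr, intron = intron_gr,
                  intergenic = inter_gr)
  expected <- vapply(cat_grs, function(g) sum(as.numeric(IRanges::width(g))),
                     0) / genome_len
  hgr <- gr(regions)
  assigned <- rep(NA_character_, nrow(regions))
  for (nm in names(cat_grs)) {
    hit <- GenomicRanges::countOverlaps(hgr, cat_grs[[nm]]) > 0
    assigned[is.na(assigned) & hit] <- nm
  }
  observed <- vapply(names(cat_grs),
                     function(nm) mean(assigned == nm, na.rm = TRUE), 0)
  data.frame(category = names(cat_grs),
             observed_fraction = unname(observed),
             expected_fraction = unname(expected),
             o_over_e = unname(observed / expected),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write hMRs as BED6+ (score = -log10 p, extra columns fold and lambda)
#' @param h An `hmr_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmrs <- function(h, path) {
  r <- h$regions
  df <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                   name = h$sample_id,
                   score = round(-log10(pmax(r$p_value, 1e-300)), 3),
                   strand = ".", fold = signif(r$fold, 5),
                   lambda = signif(r$lambda, 5))
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
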