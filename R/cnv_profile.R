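# Large-scale copy-number estimation from cfDNA fragment counts: 1-Mb bins,
# mappability filter, GC-LOESS correction, scaling to a diploid center of 2,
# capping of extreme bins, and a within-chromosome 20-Mb moving average.

#' Bin fragments at 1 Mb and filter on mappability
#'
#' Fragments are assigned to the bin containing their midpoint (one
#' fragment, one bin, so totals are conserved). Per-bin mappability and GC
#' are coverage-weighted averages of the overlapping track bins; bins with
#' mappability below `min_mappability` are marked excluded.
#'
#' @param f A [fragment_set()] (typically the input library).
#' @param tracks A `genome_tracks` object.
#' @param bin_bp Bin size (default 1e6).
#' @param min_mappability Exclusion threshold (default 0.8; bins strictly
#'   below are excluded).
#' @return Data frame: chrom, start, end, mappability, gc, raw_count,
#'   excluded, excluded_reason.
#' @export
bin_and_filter <- function(f, tracks, bin_bp = 1e6, min_mappability = 0.8) {
  stopifnot(inherits(f, "fragment_set"))
  bins <- tile_windows(tracks$chrom_sizes, bin_bp)
  bins$feature_id <- NULL
  mid <- floor((f$fragments$start + f$fragments$end) / 2)
  key <- paste0(f$fragments$chrom, ":", floor(mid / bin_bp))
  bins$raw_count <- as.numeric(table(key)[paste0(bins$chrom, ":",
                                                 floor(bins$start / bin_bp))])
  bins$raw_count[is.na(bins$raw_count)] <- 0
  bins$mappability <- .track_mean(bins, tracks$mappability)
  bins$gc <- .track_mean(bins, tracks$gc)
  bins$excluded <- bins$mappability < min_mappability
  bins$excluded_reason <- ifelse(bins$excluded, "low_mappability", "")
  if (!any(!bins$excluded)) stop("no bins retained after mappability filter")
  bins
}

# coverage-weighted mean of a scored track over each bin
.track_mean <- function(bins, track) {
  ov <- GenomicRanges::findOverlaps(as_granges0(bins), as_granges0(track))
  qi <- queryHits(ov); si <- subjectHits(ov)
  w <- pmin(bins$end[qi], track$end[si]) - pmax(bins$start[qi],
                                                track$start[si])
  num <- tapply(w * track$value[si], qi, sum)
  den <- tapply(w, qi, sum)
  out <- rep(NA_real_, nrow(bins))
  out[as.integer(names(num))] <- num / den
  out
}

#' GC-LOESS correction of binned counts
#'
#' Fits a local regression of count on GC fraction over retained bins
#' (tricube weights, degree 2) and rescales each bin by the ratio of the
#' global mean fitted value to its own fitted value. If all GC values are
#' (numerically) equal the correction is the identity.
#'
#' @param counts Numeric per-bin counts.
#' @param gc Per-bin GC fractions (same length).
#' @param span LOESS span (default 0.3).
#' @param degree Local polynomial degree (default 2).
#' @return Corrected counts (never negative).
#' @export
gc_correct <- function(counts, gc, span = 0.3, degree = 2) {
  stopifnot(length(counts) == length(gc))
  ok <- is.finite(counts) & is.finite(gc)
  if (sum(ok) < 30) stop("need at least 30 bins for GC correction")
  if (diff(range(gc[ok])) < 1e-12) return(counts)
  dat <- data.frame(x = gc[ok], y = counts[ok])
  fit <- loess(y ~ x, data = dat, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  fitted <- predict(fit, newdata = data.frame(x = gc[ok]))
  fitted <- pmax(fitted, mean(counts[ok]) * 1e-3)
  corrected <- counts
  corrected[ok] <- counts[ok] * mean(fitted) / fitted
  pmax(corrected, 0)
}

#' Scale, cap and smooth corrected bin counts into a CNV profile
#'
#' Corrected counts over retained bins are scaled so their mean is exactly 2
#' (diploid center), capped at `cap` to limit extreme bins, and smoothed
#' with a centered moving average of `smooth_bins` consecutive retained bins
#' computed within each chromosome (window truncated at chromosome ends;
#' excluded bins are skipped, not zero-filled).
#'
#' @param bins Output of [bin_and_filter()] with a `gc_corrected` column (or
#'   raw counts if no correction was applied).
#' @param cap Upper cutoff on the scaled values (default 5).
#' @param smooth_bins Moving-average window in bins (default 20, i.e. 20 Mb
#'   at 1-Mb bins).
#' @return A `cnv_profile` data frame: the input plus `scaled`, `capped`,
#'   `smoothed` (NA on excluded bins).
#' @export
scale_cap_smooth <- function(bins, cap = 5, smooth_bins = 20) {
  corr <- bins$gc_corrected %||% bins$raw_count
  keep <- !bins$excluded
  scaled <- rep(NA_real_, nrow(bins))
  scaled[keep] <- 2 * corr[keep] / mean(corr[keep])
  capped <- pmin(scaled, cap)
  smoothed <- rep(NA_real_, nrow(bins))
  half_lo <- (smooth_bins - 1) %/% 2
  half_hi <- smooth_bins %/% 2
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch & keep)
    if (!length(idx)) next
    v <- capped[idx]
    Cv <- c(0, cumsum(v))
    k <- seq_along(v)
    lo <- pmax(k - half_lo, 1L); hi <- pmin(k + half_hi, length(v))
    smoothed[idx] <- (Cv[hi + 1L] - Cv[lo]) / (hi - lo + 1L)
  }
  out <- bins
  out$scaled <- scaled
  out$capped <- capped
  out$smoothed <- smoothed
  class(out) <- c("cnv_profile", "data.frame")
  out
}

#' Estimate a copy-number profile from a fragment library
#'
#' Convenience chain: [bin_and_filter()] -> [gc_correct()] ->
#' [scale_cap_smooth()].
#'
#' @inheritParams bin_and_filter
#' @inheritParams scale_cap_smooth
#' @param span,degree Passed to [gc_correct()].
#' @return A `cnv_profile` data frame.
#' @export
estimate_cnv <- function(f, tracks, bin_bp = 1e6, min_mappability = 0.8,
                         span = 0.3, degree = 2, cap = 5, smooth_bins = 20) {
  bins <- bin_and_filter(f, tracks, bin_bp, min_mappability)
  keep <- !bins$excluded
  bins$gc_corrected <- bins$raw_count
  bins$gc_corrected[keep] <- gc_correct(bins$raw_count[keep], bins$gc[keep],
                                        span = span, degree = degree)
  scale_cap_smooth(bins, cap = cap, smooth_bins = smooth_bins)
}

#' Write a CNV profile as headered TSV
#' @param profile A `cnv_profile`.
#' @param path Output path.
#' @param provenance Optional provenance lines.
#' @return `path`, invisibly.
#' @export
write_cnv_profile <- function(profile, path, provenance = NULL) {
  cols <- c("chrom", "start", "end", "mappability", "gc", "raw_count",
            "gc_corrected", "scaled", "capped", "smoothed", "excluded_reason")
  cols <- intersect(cols, names(profile))
  write_tsv_report(as.data.frame(profile)[, cols], path, provenance)
}
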