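# Spike-in and library-level quality control for 5hmC pull-down libraries.
# Three 180-bp amplicon controls carrying C, 5mC or 5hmC are spiked into the
# cfDNA before library construction; a successful pull-down captures the
# 5hmC control far more efficiently than the other two.

#' Per-control spike-in read fractions
#'
#' @param tallies Named non-negative integer vector of reads mapped to each
#'   spike-in control.
#' @param total_mapped Reads mapped to the genome (> 0).
#' @return Named fractions `tallies / (total_mapped + sum(tallies))`; their
#'   sum is < 1.
#' @export
spike_fractions <- function(tallies, total_mapped) {
  if (any(tallies < 0)) stop("negative spike tallies")
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  tallies / (total_mapped + sum(tallies))
}

#' Spike-in fold enrichment
#'
#' Fold = pull-down fraction / input fraction; scale-invariant in library
#' depth. A zero input fraction yields `NA` (undefined), never infinity.
#'
#' @param pulldown_fraction,input_fraction Per-control fractions from
#'   [spike_fractions()].
#' @return Numeric fold-enrichment vector (`NA` where undefined).
#' @export
fold_enrichment <- function(pulldown_fraction, input_fraction) {
  fold <- ifelse(input_fraction > 0, pulldown_fraction / input_fraction,
                 NA_real_)
  if (anyNA(fold)) warning("fold enrichment undefined for zero input fraction")
  fold
}

#' Unique non-duplicate map rate
#' @param raw_count Fragments before deduplication.
#' @param after_dedup_count Fragments after deduplication (`<= raw_count`).
#' @return `after_dedup_count / raw_count`.
#' @export
unique_map_rate <- function(raw_count, after_dedup_count) {
  stopifnot(raw_count > 0, after_dedup_count >= 0,
            after_dedup_count <= raw_count)
  after_dedup_count / raw_count
}

#' Spike-in QC report for one sample
#'
#' The pass gate is deliberately permissive (a successful pull-down shows
#' ~100-fold or more 5hmC enrichment; the gate flags only clear failures):
#' pass requires 5hmC fold >= `min_hmc_fold` and 5mC/C folds <=
#' `max_other_fold`. The measured folds, not the gate, are the evidence.
#'
#' @param spike List with `pulldown` and `input` named tallies (names must
#'   include `hmC`; any other names are treated as unmodified controls).
#' @param pulldown_total,input_total Genome-mapped fragments per library.
#' @param min_hmc_fold,max_other_fold QC gate thresholds.
#' @return A `spike_report` data frame (control, modification, fractions,
#'   fold) with attributes `pass` and `sample` thresholds.
#' @export
spike_report <- function(spike, pulldown_total, input_total,
                         min_hmc_fold = 20, max_other_fold = 5) {
  stopifnot(identical(names(spike$pulldown), names(spike$input)))
  pf <- spike_fractions(spike$pulldown, pulldown_total)
  inf <- spike_fractions(spike$input, input_total)
  fold <- fold_enrichment(pf, inf)
  rep <- data.frame(control = names(pf),
                    modification = names(pf),
                    pulldown_fraction = unname(pf),
                    input_fraction = unname(inf),
                    fold_enrichment = unname(fold),
                    stringsAsFactors = FALSE)
  is_hmc <- rep$modification == "hmC"
  pass <- !anyNA(fold) &&
    all(fold[is_hmc] >= min_hmc_fold) &&
    all(fold[!is_hmc] <= max_other_fold)
  structure(rep, class = c("spike_report", "data.frame"), pass = pass,
            thresholds = c(min_hmc_fold = min_hmc_fold,
                           max_other_fold = max_other_fold))
}
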