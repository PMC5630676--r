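# Shared small synthetic cohort, built once per test run.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(
        n_per_class = c(Healthy = 4, HCC_preop = 4, Lung_M = 4),
        n_genes = 400, depth = 2e4, seed = 42))
    cache
  }
})

# manual fragment set on a toy genome (chrom sizes given separately)
toy_fragments <- function(chrom, start, end, sample_id = "toy",
                          library = "pulldown") {
  fragment_set(sample_id, library,
               data.frame(chrom = chrom, start = start, end = end,
                          stringsAsFactors = FALSE))
}
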