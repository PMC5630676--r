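# Independent brute-force oracles used to pin down expected values.

# Poisson upper tail by direct summation of the mass function to convergence
bf_poisson_tail <- function(k, lam) {
  if (k == 0) return(1)
  cap <- ceiling(max(k, lam) + 200 * sqrt(lam + 1) + 500)
  sum(stats::dpois(seq.int(k, cap), lam))
}

# O(n * m) interval overlap counting (>= 1 bp, half-open coordinates)
bf_overlap_counts <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, 0L)
}

# Benjamini-Hochberg step-down from its definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n))
    q_sorted[i] <- min(1, min(ps[i:n] * n / (i:n)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# two-sided permutation p-value for the Welch t statistic
bf_permutation_p <- function(a, b, n_perm = 1e4, seed = 1) {
  obs <- abs(welch_t(a, b)$t)
  x <- c(a, b)
  na <- length(a)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(x), na)
    t_i <- welch_t(x[idx], x[-idx])$t
    if (abs(t_i) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# random interval table for round-trip tests
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                             seed = 1) {
  set.seed(seed)
  st <- floor(runif(n, 0, max_pos - 1000))
  genomic_intervals(sample(chroms, n, TRUE), st,
                    st + 1 + floor(runif(n, 0, 999)))
}
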