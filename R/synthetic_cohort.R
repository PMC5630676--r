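# Fully synthetic genome + cohort generator with planted ground truth.
#
# The generator emulates the qualitative structure of a cell-free 5hmC
# enrichment-sequencing study: pull-down signal concentrated in gene bodies
# and scaling with expression, disease-specific genic gain/loss (HCC-like,
# pancreatic-like), stage-dependent global loss of genic enrichment
# (lung-like), chromosome-scale copy-number segments, and spike-in controls
# whose capture reflects their cytosine modification. It does not model
# sequence content, read errors, or fragment-length biology.

#' Configuration for a synthetic cfDNA 5hmC cohort
#'
#' Defaults define the study conditions used throughout the package's tests:
#' a 30-Mb three-chromosome genome with 1 200 genes and ~100 000 fragments
#' per library, with class sizes mirroring a treatment-naive plasma panel
#' (8 healthy, 7 HBV, 10 pre-op HCC plus 4 post-op and 3 recurrence
#' follow-ups, 8 non-metastatic and 7 metastatic lung, 7 pancreatic).
#'
#' @param n_per_class Named integer vector of samples per class; classes are
#'   `Healthy, HBV, HCC_preop, HCC_postop, HCC_recur, Lung_NM, Lung_M,
#'   Pancreatic`.
#' @param n_chroms,chrom_len Number of chromosomes and length of each (bp).
#' @param n_genes Number of non-overlapping genes placed on the genome.
#' @param depth Fragments per library (exact, both pull-down and input).
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution
#'   (normal, floored at 50 bp); cfDNA-like 180 +- 20 bp by default.
#' @param base_enrichment Pull-down sampling weight of a mid-tertile gene
#'   body relative to intergenic background. The default (25) concentrates
#'   genic signal enough that individual 500-bp windows are callable at the
#'   depths used here.
#' @param tertile_mult Multipliers applied to `base_enrichment` by expression
#'   tertile (low, mid, high).
#' @param spike_capture Per-modification capture probability of the three
#'   180-bp spike-in controls in the pull-down.
#' @param spike_molar_ratio Molar abundance of each spike-in control relative
#'   to genomic cfDNA fragments.
#' @param genome_capture_rate Mean capture probability of a genomic cfDNA
#'   fragment in the pull-down (the fraction carrying 5hmC); sets the spike
#'   fold-enrichment scale: `spike_capture / genome_capture_rate`.
#' @param seed Integer master seed; all randomness in the cohort derives from
#'   it (per-sample streams are obtained by hashing seed and sample id).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_class = c(Healthy = 8, HBV = 7,
                                          HCC_preop = 10, HCC_postop = 4,
                                          HCC_recur = 3, Lung_NM = 8,
                                          Lung_M = 7, Pancreatic = 7),
                          n_chroms = 3, chrom_len = 1e7, n_genes = 1200,
                          depth = 1e5,
                          fragment_len_mean = 180, fragment_len_sd = 20,
                          base_enrichment = 25,
                          tertile_mult = c(low = 0.5, mid = 1, high = 2),
                          spike_capture = c(hmC = 0.5, mC = 0.004, C = 0.004),
                          spike_molar_ratio = 2e-3,
                          genome_capture_rate = 0.0015,
                          seed = 1) {
  stopifnot(all(n_per_class >= 0), depth > 0, n_chroms >= 1, chrom_len > 0,
            n_genes >= 0, base_enrichment > 0,
            all(spike_capture > 0), all(spike_capture <= 1))
  structure(list(n_per_class = n_per_class, n_chroms = n_chroms,
                 chrom_len = chrom_len, n_genes = n_genes, depth = depth,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 base_enrichment = base_enrichment,
                 tertile_mult = tertile_mult,
                 spike_capture = spike_capture,
                 spike_molar_ratio = spike_molar_ratio,
                 genome_capture_rate = genome_capture_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-stream seed: polynomial rolling hash of the master seed
# and a stream label, kept below 2^31.
hash_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome with tracks and gene models
#'
#' Chromosomes are tiled with 1-kb GC and mappability bins (GC ~ Beta with
#' mean 0.41; mappability 1.0 except ~5% of bins drawn below 0.8), genes are
#' placed uniformly without overlap with log-normal lengths (>= 1 kb), each
#' with 1-4 disjoint exons, and ~1% of the genome is blacklisted.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `synthetic_genome` with `tracks` (chrom_sizes,
#'   gc, mappability, blacklist), `genes`, and a precomputed `segments`
#'   table used by [simulate_sample()].
#' @export
generate_genome <- function(cfg) {
  with_seed(hash_seed(cfg$seed, "genome"), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    chrom_sizes <- setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms)

    bin <- 1000
    nb <- ceiling(cfg$chrom_len / bin)
    bins <- genomic_intervals(rep(chroms, each = nb),
                              rep(seq_len(nb) - 1, cfg$n_chroms) * bin,
                              pmin(rep(seq_len(nb), cfg$n_chroms) * bin,
                                   cfg$chrom_len))
    ntot <- nrow(bins)
    gc <- rbeta(ntot, 0.41 * 60, 0.59 * 60)
    low <- rbinom(ntot, 1, 0.05) == 1
    map <- ifelse(low, runif(ntot, 0.3, 0.8 - 1e-9), 1.0)
    gc_track <- bins; gc_track$value <- gc
    map_track <- bins; map_track$value <- map

    # blacklist ~1% of each chromosome in 10-kb pieces, 1-kb aligned
    bl <- list()
    for (ch in chroms) {
      nblk <- max(1L, round(0.01 * cfg$chrom_len / 1e4))
      st <- sort(sample.int(floor(cfg$chrom_len / bin) - 10, nblk)) * bin
      bl[[ch]] <- data.frame(chrom = ch, start = st, end = st + 1e4)
    }
    blacklist <- reduce_intervals(do.call(rbind, bl))

    genes <- place_genes(cfg, chroms)
    tracks <- structure(list(chrom_sizes = chrom_sizes, gc = gc_track,
                             mappability = map_track, blacklist = blacklist),
                        class = "genome_tracks")
    segments <- build_segments(tracks, genes)
    structure(list(tracks = tracks, genes = genes, segments = segments,
                   config = cfg),
              class = "synthetic_genome")
  })
}

place_genes <- function(cfg, chroms) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), exon_starts = character(0),
                      exon_ends = character(0), length_bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_genes == 0) return(empty)
  lens <- pmax(1000, round(rlnorm(cfg$n_genes, log(2500), 0.45)))
  chrom_of <- sample(chroms, cfg$n_genes, replace = TRUE)
  out <- list()
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    L <- lens[idx]
    free <- cfg$chrom_len - sum(L)
    if (free < 0.05 * cfg$chrom_len)
      stop("genome too small to place ", cfg$n_genes, " genes")
    gaps <- rexp(length(L) + 1)
    gaps <- floor(gaps / sum(gaps) * free)
    starts <- cumsum(gaps[seq_along(L)] + c(0, L[-length(L)]))
    out[[ch]] <- data.frame(gene_id = sprintf("g%04d", idx), chrom = ch,
                            start = starts, end = starts + L,
                            strand = sample(c("+", "-"), length(L), TRUE),
                            stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  genes <- genes[order(genes$gene_id), ]
  # 1-4 disjoint exons per gene, each the middle part of an equal split
  nex <- sample(1:4, nrow(genes), replace = TRUE)
  exs <- character(nrow(genes)); exe <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    k <- nex[i]
    bounds <- round(seq(genes$start[i], genes$end[i], length.out = k + 1))
    w <- bounds[-1] - bounds[-(k + 1)]
    frac <- runif(k, 0.3, 0.8)
    es <- bounds[-(k + 1)] + floor(w * (1 - frac) / 2)
    ee <- pmin(es + pmax(1, floor(w * frac)), bounds[-1])
    exs[i] <- paste(es, collapse = ",")
    exe[i] <- paste(ee, collapse = ",")
  }
  genes$exon_starts <- exs
  genes$exon_ends <- exe
  genes$length_bp <- genes$end - genes$start
  # Each gene's 5hmC mass is concentrated in one fixed ~600-bp peak (hMR-like
  # subregion), as in real hydroxymethylomes; the peak position is a genomic
  # property shared by all samples.
  pw <- pmin(600, genes$length_bp)
  genes$peak_start <- genes$start +
    floor(runif(nrow(genes)) * (genes$length_bp - pw + 1))
  genes$peak_end <- genes$peak_start + pw
  rownames(genes) <- NULL
  validate_gene_models(genes)
}

#' Merge overlapping or adjacent intervals
#' @param df Interval `data.frame`.
#' @return Sorted, disjoint interval `data.frame`.
#' @export
reduce_intervals <- function(df) {
  if (nrow(df) == 0) return(sort_intervals(df[, c("chrom", "start", "end")]))
  g <- GenomicRanges::reduce(as_granges0(df))
  genomic_intervals(as.character(GenomicRanges::seqnames(g)),
                    GenomicRanges::start(g) - 1, GenomicRanges::end(g))
}

# Piecewise-constant segmentation of the genome at every 1-kb track boundary
# plus every gene boundary; sampling weights are constant within a segment.
build_segments <- function(tracks, genes) {
  segs <- list()
  for (ch in names(tracks$chrom_sizes)) {
    len <- tracks$chrom_sizes[[ch]]
    gch <- genes$chrom == ch
    bp <- sort(unique(c(seq(0, len, by = 1000), len,
                        genes$start[gch], genes$end[gch],
                        genes$peak_start[gch], genes$peak_end[gch])))
    bp <- bp[bp >= 0 & bp <= len]
    st <- bp[-length(bp)]; en <- bp[-1]
    keep <- en > st
    st <- st[keep]; en <- en[keep]
    map <- tracks$mappability$value[tracks$mappability$chrom == ch]
    seg_map <- map[pmin(floor(st / 1000) + 1, length(map))]
    gene_row <- rep(NA_integer_, length(st))
    gi <- which(genes$chrom == ch)
    if (length(gi)) {
      # genes are non-overlapping; assign by segment start position
      fi <- findInterval(st, genes$start[gi])
      hit <- fi >= 1 & st < genes$end[gi][pmax(fi, 1)]
      gene_row[hit] <- gi[fi[hit]]
    }
    in_peak <- rep(FALSE, length(st))
    if (!is.null(genes$peak_start)) {
      g <- which(!is.na(gene_row))
      in_peak[g] <- st[g] >= genes$peak_start[gene_row[g]] &
        en[g] <= genes$peak_end[gene_row[g]]
    }
    segs[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                             len = en - st, map = seg_map,
                             gene_row = gene_row, in_peak = in_peak,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------

.cohort_classes <- c("Healthy", "HBV", "HCC_preop", "HCC_postop", "HCC_recur",
                     "Lung_NM", "Lung_M", "Pancreatic")

#' Build the planted ground truth for a synthetic cohort
#'
#' Defines, deterministically from the config seed: per-gene expression
#' tertiles and RPKM values; HCC-like (300 up / 500 down, |log2FC| = 1) and
#' pancreatic-like (350 / 350) differential gene sets; an HBV profile of 50
#' HCC-overlapping genes at half effect; global genic-loss factors
#' (lung-like: 0.6 non-metastatic, 0.2 metastatic); per-class chromosome-scale
#' copy-number segments; and the spike-in capture model. Post-op HCC carries
#' the healthy profile, recurrence the HCC profile.
#'
#' @param genome A [generate_genome()] result.
#' @param cfg The same [cohort_config()].
#' @param extra_regions Optional interval `data.frame` with a `fold` column:
#'   additional enriched regions planted on top of the genic model (used for
#'   peak-calling benchmarks).
#' @return A `synthetic_truth` list.
#' @export
make_truth <- function(genome, cfg, extra_regions = NULL) {
  genes <- genome$genes
  with_seed(hash_seed(cfg$seed, "truth"), {
    n <- nrow(genes)
    tert <- rep("mid", n)
    rpkm <- numeric(n)
    if (n >= 3) {
      o <- sample.int(n)
      third <- floor(n / 3)
      tert[o[seq_len(third)]] <- "low"
      tert[o[seq.int(n - third + 1, n)]] <- "high"
    }
    mean_rpkm <- c(low = 1, mid = 5, high = 25)
    rpkm <- rlnorm(n, log(mean_rpkm[tert]), 0.3)
    expression <- data.frame(gene_id = genes$gene_id, tertile = tert,
                             rpkm = rpkm, stringsAsFactors = FALSE)

    profiles <- list()
    if (n >= 800) {
      hcc_genes <- sample(genes$gene_id, 800)
      profiles$HCC <- data.frame(gene_id = hcc_genes,
                                 log2fc = rep(c(1, -1), c(300, 500)),
                                 stringsAsFactors = FALSE)
      hbv_genes <- sample(hcc_genes, min(50, length(hcc_genes)))
      hbv <- profiles$HCC[match(hbv_genes, profiles$HCC$gene_id), ]
      hbv$log2fc <- hbv$log2fc / 2
      profiles$HBV <- hbv
      panc_genes <- sample(genes$gene_id, 700)
      profiles$Pancreatic <- data.frame(gene_id = panc_genes,
                                        log2fc = rep(c(1, -1), c(350, 350)),
                                        stringsAsFactors = FALSE)
    }
    class_profile <- c(Healthy = "none", HBV = "HBV", HCC_preop = "HCC",
                       HCC_postop = "none", HCC_recur = "HCC",
                       Lung_NM = "none", Lung_M = "none",
                       Pancreatic = "Pancreatic")
    loss_factor <- c(Healthy = 1, HBV = 1, HCC_preop = 1, HCC_postop = 1,
                     HCC_recur = 1, Lung_NM = 0.6, Lung_M = 0.2,
                     Pancreatic = 1)
    chroms <- names(genome$tracks$chrom_sizes)
    cnv <- list()
    if (length(chroms) >= 3) {
      L <- genome$tracks$chrom_sizes[[1]]
      cnv$HCC_preop <- data.frame(chrom = chroms[1], start = 0,
                                  end = 0.3 * L, copy = 2.5)
      cnv$HCC_recur <- cnv$HCC_preop
      cnv$Pancreatic <- data.frame(chrom = chroms[2], start = 0.5 * L,
                                   end = L, copy = 1.5)
      cnv$Lung_M <- data.frame(chrom = chroms[3], start = 0, end = 0.5 * L,
                               copy = 3)
    }
    if (!is.null(extra_regions)) {
      stopifnot(!is.null(extra_regions$fold))
      validate_intervals(extra_regions, "extra_regions")
    }
    structure(list(expression = expression, profiles = profiles,
                   class_profile = class_profile, loss_factor = loss_factor,
                   cnv = cnv, spike_capture = cfg$spike_capture,
                   enriched_regions = extra_regions),
              class = "synthetic_truth")
  })
}

#' Simulate one sample's pull-down and input libraries
#'
#' Input fragments are drawn with per-bp weight proportional to local copy
#' number and mappability. Pull-down fragments additionally weight gene
#' bodies by `loss_factor * base_enrichment * tertile_mult * 2^log2FC` (and
#' any extra planted regions by their fold); intergenic background has
#' weight 1. Fragment midpoints are placed uniformly within the sampled
#' segment and extended to a normal fragment length. Spike-in read tallies
#' are drawn from the capture model. Exactly `cfg$depth` fragments per
#' library; deterministic given (cfg$seed, sample_id).
#'
#' @param class_label One of the cohort classes.
#' @param sample_id Unique sample label (seeds the sample's RNG streams).
#' @param truth A [make_truth()] object.
#' @param genome A [generate_genome()] object.
#' @param cfg The [cohort_config()].
#' @return List with `pulldown` and `input` [fragment_set()]s and `spike`
#'   (per-library named tallies for the hmC/mC/C controls).
#' @export
simulate_sample <- function(class_label, sample_id, truth, genome, cfg) {
  if (!class_label %in% .cohort_classes)
    stop("unknown class label: ", class_label)
  segs <- genome$segments
  genes <- genome$genes

  # per-gene pull-down enrichment for this class
  E <- rep(1, nrow(genes))
  if (nrow(genes)) {
    tm <- cfg$tertile_mult[truth$expression$tertile]
    fc <- rep(0, nrow(genes))
    prof <- truth$class_profile[[class_label]]
    if (!is.null(prof) && prof != "none" && !is.null(truth$profiles[[prof]])) {
      p <- truth$profiles[[prof]]
      fc[match(p$gene_id, genes$gene_id)] <- p$log2fc
    }
    E <- truth$loss_factor[[class_label]] * cfg$base_enrichment * tm * 2^fc
  }
  seg_int <- rep(1, nrow(segs))
  hit <- which(!is.na(segs$gene_row))
  if (is.null(genes$peak_start)) {
    seg_int[hit] <- E[segs$gene_row[hit]]
  } else {
    # whole-body average intensity is E_g, but the mass sits in the gene's
    # peak: peak intensity 1 + (E_g - 1) * len / width, baseline 1 elsewhere
    len <- genes$end - genes$start
    w <- genes$peak_end - genes$peak_start
    peak_int <- pmax(1 + (E - 1) * len / w, 0.01)
    gidx <- segs$gene_row[hit]
    seg_int[hit] <- ifelse(segs$in_peak[hit], peak_int[gidx], 1)
  }
  if (!is.null(truth$enriched_regions)) {
    ov <- GenomicRanges::findOverlaps(as_granges0(segs),
                                      as_granges0(truth$enriched_regions))
    seg_int[queryHits(ov)] <-
      seg_int[queryHits(ov)] * truth$enriched_regions$fold[subjectHits(ov)]
  }
  copy <- rep(2, nrow(segs))
  cnv <- truth$cnv[[class_label]]
  if (!is.null(cnv)) {
    for (i in seq_len(nrow(cnv))) {
      in_seg <- segs$chrom == cnv$chrom[i] & segs$start >= cnv$start[i] &
        segs$end <= cnv$end[i]
      copy[in_seg] <- cnv$copy[i]
    }
  }
  w_input <- segs$len * segs$map * copy
  w_pd <- w_input * seg_int

  draw <- function(w, lib) {
    with_seed(hash_seed(cfg$seed, sample_id, lib), {
      idx <- sample.int(nrow(segs), cfg$depth, replace = TRUE, prob = w)
      mid <- segs$start[idx] + floor(runif(cfg$depth) * segs$len[idx])
      flen <- pmax(50, round(rnorm(cfg$depth, cfg$fragment_len_mean,
                                   cfg$fragment_len_sd)))
      st <- mid - floor(flen / 2)
      en <- st + flen
      clen <- genome$tracks$chrom_sizes[segs$chrom[idx]]
      st <- pmax(0, st)
      en <- pmin(en, clen)
      en <- pmax(en, st + 1)
      fragment_set(sample_id, lib,
                   data.frame(chrom = segs$chrom[idx], start = st, end = en,
                              stringsAsFactors = FALSE))
    })
  }
  pulldown <- draw(w_pd, "pulldown")
  input <- draw(w_input, "input")

  spike <- with_seed(hash_seed(cfg$seed, sample_id, "spike"), {
    m <- cfg$spike_molar_ratio
    caps <- truth$spike_capture
    in_rate <- rep(m / (1 + length(caps) * m), length(caps))
    pd_rate <- m * caps / (cfg$genome_capture_rate + sum(m * caps))
    list(pulldown = setNames(rbinom(length(caps), cfg$depth, pd_rate),
                             names(caps)),
         input = setNames(rbinom(length(caps), cfg$depth, in_rate),
                          names(caps)))
  })
  list(class = class_label, sample_id = sample_id,
       pulldown = pulldown, input = input, spike = spike)
}

#' Simulate a full labeled cohort
#'
#' @param cfg A [cohort_config()].
#' @param extra_regions Passed to [make_truth()].
#' @return A `synthetic_cohort` list with `genome`, `truth`, `samples` (list
#'   of [simulate_sample()] results) and `labels` (data frame of sample_id,
#'   class).
#' @export
simulate_cohort <- function(cfg = cohort_config(), extra_regions = NULL) {
  genome <- generate_genome(cfg)
  truth <- make_truth(genome, cfg, extra_regions)
  samples <- list()
  for (cl in names(cfg$n_per_class)) {
    k <- cfg$n_per_class[[cl]]
    if (k <= 0) next
    for (i in seq_len(k)) {
      sid <- sprintf("%s_%02d", cl, i)
      samples[[sid]] <- simulate_sample(cl, sid, truth, genome, cfg)
    }
  }
  labels <- data.frame(sample_id = names(samples),
                       class = vapply(samples, `[[`, "", "class"),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genome = genome, truth = truth, samples = samples,
                 labels = labels, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d genes, %d chromosome(s) x %g Mb, depth %g\n",
              length(x$samples), nrow(x$genome$genes),
              x$config$n_chroms, x$config$chrom_len / 1e6, x$config$depth))
  print(table(x$labels$class))
  invisible(x)
}

#' Export the planted truth as a TSV
#' @param cohort A [simulate_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  tr <- cohort$truth
  rows <- list()
  for (nm in names(tr$profiles)) {
    p <- tr$profiles[[nm]]
    rows[[nm]] <- data.frame(kind = "differential_gene", id = p$gene_id,
                             class = nm, value = p$log2fc)
  }
  rows$loss <- data.frame(kind = "loss_factor", id = names(tr$loss_factor),
                          class = names(tr$loss_factor),
                          value = unname(tr$loss_factor))
  rows$tert <- data.frame(kind = "expression_rpkm", id = tr$expression$gene_id,
                          class = tr$expression$tertile,
                          value = tr$expression$rpkm)
  write_tsv_report(do.call(rbind, rows), path)
}
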