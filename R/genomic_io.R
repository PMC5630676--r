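# Genomic interval plumbing. All coordinates are 0-based half-open (BED
# convention) everywhere inside the package; conversion to the 1-based closed
# convention happens only at the GRanges boundary.

#' Construct a validated table of genomic intervals
#'
#' The package-wide interval container is a plain `data.frame` with columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#' Intervals are returned sorted by (chrom, start, end) using a
#' locale-independent radix order.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors; `start >= 0`, `end > start`.
#' @param strand Optional character vector in `c("+", "-", "*")`.
#' @param ... Additional columns recycled alongside the coordinates.
#' @return A sorted `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  sort_intervals(df)
}

validate_intervals <- function(df, context = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop(context, ": need columns chrom, start, end")
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(context, ": empty chromosome name")
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop(context, ": non-finite coordinates")
  if (any(df$start < 0)) stop(context, ": negative start coordinate")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(context, ": end <= start at row ", bad[1])
  invisible(df)
}

sort_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  o <- order(df$chrom, df$start, df$end, method = "radix")
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert an interval table to GRanges
#'
#' Internal boundary to the Bioconductor overlap machinery: 0-based half-open
#' `[start, end)` becomes 1-based closed `[start+1, end]`, so adjacent
#' (touching) intervals do not overlap.
#' @param df Interval `data.frame`.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
as_granges0 <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Count overlaps between two interval tables
#'
#' A query interval and subject interval overlap when they share at least 1 bp.
#' @param query,subject Interval `data.frame`s.
#' @return Integer vector, one count per row of `query`.
#' @export
count_interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject))
}

#' Read a BED file
#'
#' Parses BED3/BED6 as 0-based half-open intervals. Comment (`#`), `track`,
#' `browser` and blank lines are skipped. Malformed lines raise an error that
#' names the offending line number.
#'
#' @param path Path to a whitespace-delimited BED file.
#' @param kind `"intervals"` (default) or `"scored"`; `"scored"` requires a
#'   numeric 5th column which is returned as column `score`.
#' @return Sorted interval `data.frame`; for BED6 input, `name`, `score` and
#'   `strand` columns are kept.
#' @export
read_bed <- function(path, kind = c("intervals", "scored")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("line ", idx[bad[1]], ": invalid interval (end <= start or start < 0)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5)) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (kind == "scored" && anyNA(score))
      stop("line ", idx[which(is.na(score))[1]], ": non-numeric score")
    df$score <- score
  } else if (kind == "scored") {
    stop("scored BED requires >= 5 columns")
  }
  if (all(nf >= 6)) df$strand <- vapply(fields, `[[`, "", 6L)
  sort_intervals(df)
}

#' Write intervals as BED
#'
#' @param x Interval `data.frame`; optional `name`, `score`, `strand` columns
#'   are written as BED6.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    x$name <- if (is.null(x$name)) "." else x$name
    x$score <- if (is.null(x$score)) 0 else x$score
    x$strand <- if (is.null(x$strand)) "*" else x$strand
    cols <- c(cols, "name", "score", "strand")
  }
  out <- x[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a fragment set
#'
#' One sequencing library of aligned, extended fragments. The unit is the
#' sequenced cfDNA fragment (not the read): each row is one fragment interval.
#' Strand is ignored for all counting.
#'
#' @param sample_id Sample label.
#' @param library `"pulldown"` (5hmC-enriched) or `"input"` (unenriched).
#' @param fragments Interval `data.frame`.
#' @return An object of class `fragment_set` with elements `sample_id`,
#'   `library`, `fragments` (sorted) and `total_mapped`.
#' @export
fragment_set <- function(sample_id, library = c("pulldown", "input"),
                         fragments) {
  library <- match.arg(library)
  validate_intervals(fragments, "fragments")
  fragments <- sort_intervals(fragments[, c("chrom", "start", "end")])
  structure(list(sample_id = as.character(sample_id), library = library,
                 fragments = fragments, total_mapped = nrow(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s [%s]: %d fragments on %d chromosome(s)\n",
              x$sample_id, x$library, x$total_mapped,
              length(unique(x$fragments$chrom))))
  invisible(x)
}

#' Collapse duplicate fragments
#'
#' Fragments with identical (chrom, start, end) are collapsed to a single
#' representative, a desk-scale proxy for `samtools rmdup` on positionally
#' duplicated read pairs.
#'
#' @param f A [fragment_set()].
#' @return A list with `fragments` (deduplicated `fragment_set`) and
#'   `duplicate_rate` (= 1 - unique/total; 0 for an empty library).
#' @export
deduplicate_fragments <- function(f) {
  stopifnot(inherits(f, "fragment_set"))
  fr <- f$fragments
  if (nrow(fr) == 0)
    return(list(fragments = f, duplicate_rate = 0))
  dup <- duplicated(fr[, c("chrom", "start", "end")])
  uniq <- fr[!dup, , drop = FALSE]
  list(fragments = fragment_set(f$sample_id, f$library, uniq),
       duplicate_rate = 1 - nrow(uniq) / nrow(fr))
}

#' Write a per-bin track as bedGraph
#'
#' Bins must tile each chromosome without overlap. When `total_mapped` is
#' given, raw per-bin counts are normalized to fragments-per-million:
#' `value = count * 1e6 / total_mapped`.
#'
#' @param bins Interval `data.frame` with a `value` (or `count`) column.
#' @param path Output path.
#' @param total_mapped Optional library size used to normalize `count`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, path, total_mapped = NULL) {
  validate_intervals(bins, "bins")
  bins <- sort_intervals(bins)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch)
  }
  value <- if (!is.null(total_mapped)) {
    stopifnot(!is.null(bins$count), total_mapped > 0)
    bins$count * 1e6 / total_mapped
  } else {
    stopifnot(!is.null(bins$value))
    bins$value
  }
  lines <- sprintf("%s\t%s\t%s\t%.10g", bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE), value)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track
#' @param path Path to a 4-column bedGraph file.
#' @return Sorted interval `data.frame` with a numeric `value` column.
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path, kind = "intervals")
  if (is.null(df$name)) stop("bedGraph requires 4 columns")
  df$value <- suppressWarnings(as.numeric(df$name))
  if (anyNA(df$value)) stop("non-numeric bedGraph value")
  df$name <- NULL
  df
}

#' Write gene models as a tab-delimited table
#'
#' Columns: gene_id, chrom, start, end, strand, exon_starts, exon_ends
#' (comma-separated, 0-based half-open). The header line starts with `#`.
#' @param genes Gene model `data.frame` (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  cols <- c("gene_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends")
  stopifnot(all(cols %in% names(genes)))
  out <- genes[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  write.table(format(out, scientific = FALSE, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' @param path Path written by [write_gene_models()].
#' @return A `data.frame` with columns gene_id, chrom, start, end, strand,
#'   exon_starts, exon_ends and derived `length_bp`. Exons are validated to be
#'   pairwise disjoint and contained in the gene body.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "", skip = 1,
                   col.names = c("gene_id", "chrom", "start", "end", "strand",
                                 "exon_starts", "exon_ends"),
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "character", "character",
                                  "character"))
  df$length_bp <- df$end - df$start
  validate_gene_models(df)
}

validate_gene_models <- function(genes) {
  validate_intervals(genes, "gene bodies")
  if (is.null(genes$length_bp)) genes$length_bp <- genes$end - genes$start
  for (i in seq_len(nrow(genes))) {
    es <- parse_num_list(genes$exon_starts[i])
    ee <- parse_num_list(genes$exon_ends[i])
    if (length(es) != length(ee)) stop("exon start/end length mismatch for ",
                                       genes$gene_id[i])
    if (length(es)) {
      o <- order(es)
      es <- es[o]; ee <- ee[o]
      if (any(ee <= es) || any(es < genes$start[i]) || any(ee > genes$end[i]))
        stop("exon outside gene body for ", genes$gene_id[i])
      if (length(es) > 1 && any(es[-1] < ee[-length(ee)]))
        stop("overlapping exons for ", genes$gene_id[i])
    }
  }
  genes
}

parse_num_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Expand gene exons into one interval table
#' @param genes Gene model `data.frame`.
#' @return Interval `data.frame` with a `gene_id` column, one row per exon.
#' @export
gene_exons <- function(genes) {
  if (nrow(genes) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  es <- lapply(genes$exon_starts, parse_num_list)
  ee <- lapply(genes$exon_ends, parse_num_list)
  n <- lengths(es)
  genomic_intervals(rep(genes$chrom, n), unlist(es), unlist(ee),
                    gene_id = rep(genes$gene_id, n))
}

#' Write a generic data frame as headered TSV
#'
#' All tabular pipeline outputs share this format: `#`-prefixed provenance
#' lines, then a `#`-prefixed header, then tab-delimited rows.
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Optional character vector of `key=value` strings echoed
#'   as leading comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
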