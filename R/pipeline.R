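# End-to-end orchestration: synthetic cohort -> QC -> peaks -> quantify ->
# differential -> CNV -> classification, with deterministic, provenance-
# stamped TSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one object. Defaults
#' are the package-wide analysis settings: hMR calling at Poisson p < 1e-5
#' in 500-bp windows stepped by 100 bp, differential selection at q < 0.001
#' with fold change > 1.41, CNV bins of 1 Mb filtered at mappability 0.8
#' with cap 5 and a 20-bin moving average, and top-5-per-comparison feature
#' selection with random-forest seed 5.
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort.
#' @param stages Character vector of stages to run, from
#'   `simulate, qc, callpeaks, quantify, diff, cnv, classify`.
#' @param hmr_window_bp,hmr_step_bp,hmr_p_cutoff Peak-calling parameters.
#' @param diff_q_max,diff_fc_min Differential-gene selection thresholds.
#' @param min_mappability,cnv_cap,cnv_smooth_bins CNV parameters.
#' @param k_top,rf_seed Classification parameters.
#' @param peak_samples How many samples (from the start of the cohort) to
#'   call peaks on; `Inf` for all.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            stages = c("simulate", "qc", "callpeaks",
                                       "quantify", "diff", "cnv",
                                       "classify"),
                            hmr_window_bp = 500, hmr_step_bp = 100,
                            hmr_p_cutoff = 1e-5,
                            diff_q_max = 0.001, diff_fc_min = 1.41,
                            min_mappability = 0.8, cnv_cap = 5,
                            cnv_smooth_bins = 20,
                            k_top = 5, rf_seed = 5, peak_samples = 6) {
  structure(list(cohort = cohort, stages = stages,
                 hmr_window_bp = hmr_window_bp, hmr_step_bp = hmr_step_bp,
                 hmr_p_cutoff = hmr_p_cutoff, diff_q_max = diff_q_max,
                 diff_fc_min = diff_fc_min,
                 min_mappability = min_mappability, cnv_cap = cnv_cap,
                 cnv_smooth_bins = cnv_smooth_bins, k_top = k_top,
                 rf_seed = rf_seed, peak_samples = peak_samples),
            class = "pipeline_config")
}

.flat_params <- function(config) {
  p <- config[setdiff(names(config), c("cohort", "stages"))]
  c(paste0("seed=", config$cohort$seed),
    paste0("depth=", config$cohort$depth),
    vapply(names(p), function(k) paste0(k, "=", paste(p[[k]], collapse = ",")),
           ""))
}

#' Run the pipeline
#'
#' Executes the requested stages in order and writes provenance-stamped
#' artifacts into `out_dir`. Later stages consume in-memory results of
#' earlier ones; requesting a stage without its prerequisite raises an error
#' naming the missing artifact. Reruns with the same config are
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(cohort = unclass(config$cohort)[
    setdiff(names(config$cohort), "n_per_class")],
    n_per_class = as.list(config$cohort$n_per_class),
    params = unclass(config)[setdiff(names(config), c("cohort", "stages"))],
    stages = config$stages), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  prov <- c(paste0("config_md5=", hash), .flat_params(config))
  stages <- config$stages
  need <- function(stage, prereq, what) {
    if (!prereq %in% stages)
      stop("stage '", stage, "' requires artifact '", what,
           "' from stage '", prereq, "'")
  }
  res <- list(config = config, config_md5 = hash)

  if ("simulate" %in% stages) {
    say("simulate: generating cohort (seed %d)", config$cohort$seed)
    res$cohort <- simulate_cohort(config$cohort)
    write_truth(res$cohort, file.path(out_dir, "truth.tsv"))
    write_gene_models(res$cohort$genome$genes,
                      file.path(out_dir, "genes.tsv"))
    write_bed(res$cohort$genome$tracks$blacklist,
              file.path(out_dir, "blacklist.bed"))
  }

  if ("qc" %in% stages) {
    need("qc", "simulate", "cohort")
    say("qc: spike-in enrichment for %d samples", length(res$cohort$samples))
    qc <- lapply(res$cohort$samples, function(s) {
      rep <- spike_report(s$spike, s$pulldown$total_mapped,
                          s$input$total_mapped)
      cbind(sample_id = s$sample_id, as.data.frame(rep),
            pass = attr(rep, "pass"))
    })
    res$qc <- do.call(rbind, c(qc, make.row.names = FALSE))
    write_tsv_report(res$qc, file.path(out_dir, "spike_qc.tsv"), prov)
  }

  if ("callpeaks" %in% stages) {
    need("callpeaks", "simulate", "cohort")
    ids <- head(names(res$cohort$samples), config$peak_samples)
    say("callpeaks: %d samples", length(ids))
    cs <- res$cohort$genome$tracks$chrom_sizes
    res$hmrs <- lapply(res$cohort$samples[ids], function(s)
      call_hmrs(s$pulldown, s$input, cs,
                window_bp = config$hmr_window_bp,
                step_bp = config$hmr_step_bp,
                p_cutoff = config$hmr_p_cutoff))
    for (id in ids)
      write_hmrs(res$hmrs[[id]], file.path(out_dir,
                                           paste0("hmrs_", id, ".bed")))
    summ <- data.frame(sample_id = ids,
                       class = res$cohort$labels$class[match(ids,
                         res$cohort$labels$sample_id)],
                       n_hmrs = vapply(res$hmrs, function(h)
                         nrow(h$regions), 0),
                       n_per_million = vapply(res$hmrs, `[[`, 0,
                                              "n_per_million"))
    write_tsv_report(summ, file.path(out_dir, "hmr_summary.tsv"), prov)
    res$annotation <- annotate_hmrs(res$hmrs[[1]], res$cohort$genome$genes,
                                    cs)
    write_tsv_report(res$annotation,
                     file.path(out_dir, "hmr_annotation.tsv"), prov)
  }

  if ("quantify" %in% stages) {
    need("quantify", "simulate", "cohort")
    say("quantify: gene-body FPKM matrix")
    res$gene_matrix <- build_feature_matrix(res$cohort, "gene_body")
    mat <- data.frame(feature_id = rownames(res$gene_matrix),
                      signif(res$gene_matrix, 6), check.names = FALSE)
    write_tsv_report(mat, file.path(out_dir, "gene_fpkm.tsv"), prov)
  }

  if ("diff" %in% stages) {
    need("diff", "quantify", "gene FPKM matrix")
    say("diff: per-class differential genes vs healthy")
    lab <- res$cohort$labels$class
    res$diff <- list()
    for (cl in c("HCC_preop", "Lung_M", "Pancreatic")) {
      keep <- lab %in% c("Healthy", cl)
      if (sum(lab == cl) < 2) next
      dr <- moderated_t(res$gene_matrix[, keep, drop = FALSE], lab[keep],
                        ref = "Healthy")
      sel <- select_differential(dr, config$diff_q_max, config$diff_fc_min)
      res$diff[[cl]] <- list(result = dr, selection = sel)
      out <- dr
      out[-1] <- lapply(out[-1], signif, 6)
      write_tsv_report(out, file.path(out_dir,
                                      paste0("diff_", cl, "_vs_healthy.tsv")),
                       c(prov, paste0("n_selected=",
                                      nrow(sel$selected))))
    }
  }

  if ("cnv" %in% stages) {
    need("cnv", "simulate", "cohort")
    say("cnv: input-library profiles")
    tracks <- res$cohort$genome$tracks
    prof <- lapply(res$cohort$samples, function(s)
      cbind(sample_id = s$sample_id,
            as.data.frame(estimate_cnv(s$input, tracks,
                                       min_mappability = config$min_mappability,
                                       cap = config$cnv_cap,
                                       smooth_bins = config$cnv_smooth_bins))))
    res$cnv <- do.call(rbind, c(prof, make.row.names = FALSE))
    num <- vapply(res$cnv, is.numeric, TRUE)
    res$cnv[num] <- lapply(res$cnv[num], function(x) signif(x, 6))
    write_tsv_report(res$cnv, file.path(out_dir, "cnv_profiles.tsv"), prov)
  }

  if ("classify" %in% stages) {
    need("classify", "quantify", "gene FPKM matrix")
    say("classify: LOO cross-validation (mclust + random forest)")
    lab <- res$cohort$labels$class
    keep <- lab %in% c("Healthy", "HCC_preop", "Pancreatic", "Lung_NM",
                       "Lung_M")
    mat <- res$gene_matrix[, keep, drop = FALSE]
    y <- ifelse(lab[keep] == "HCC_preop", "HCC", lab[keep])
    mc <- loo_cross_validate(mat, y, classifier = "mclust",
                             k_top = config$k_top)
    rf <- loo_cross_validate(mat, y, classifier = "rf",
                             k_top = config$k_top, rf_seed = config$rf_seed)
    kap <- list(mc_vs_rf = cohens_kappa(mc$predictions$predicted,
                                        rf$predictions$predicted),
                mc_vs_truth = cohens_kappa(mc$predictions$predicted, y),
                rf_vs_truth = cohens_kappa(rf$predictions$predicted, y))
    res$classify <- list(mclust = mc, rf = rf, kappa = kap)
    preds <- data.frame(sample_id = mc$predictions$sample_id, true = y,
                        mclust = mc$predictions$predicted,
                        rf = rf$predictions$predicted)
    write_tsv_report(preds, file.path(out_dir, "loo_predictions.tsv"), prov)
    jsonlite::write_json(
      list(config_md5 = hash,
           accuracy = list(mclust = mc$accuracy, rf = rf$accuracy,
                           mclust_type_only = mc$accuracy_type_only,
                           rf_type_only = rf$accuracy_type_only),
           kappa = lapply(kap, function(k)
             list(kappa = k$kappa, ci = k$ci))),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("done: %s", out_dir)
  invisible(res)
}

#' One-command demo on the default synthetic cohort
#'
#' Builds the default cohort and runs every stage.
#' @param out_dir Output directory.
#' @param seed Cohort master seed.
#' @param depth Fragments per library.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
demo_pipeline <- function(out_dir, seed = 1, depth = 1e5, quiet = FALSE) {
  cfg <- pipeline_config(cohort = cohort_config(seed = seed, depth = depth))
  run_pipeline(cfg, out_dir, quiet = quiet)
}
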