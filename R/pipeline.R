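#' Run the fragment-to-clock pipeline on a simulated cohort
#'
#' Executes the complete analysis path — simulate, consensus peakset,
#' cut-site counting, QC (depth, FRIP, robust-PCA outliers), normalization,
#' genome-wide age correlations, and nested cross-validated clock training —
#' and writes plain-text outputs to `out_dir`. Everything is driven by the
#' config seed, so a fixed config reproduces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [fragment_config()].
#' @param min_samples Consensus reliability threshold; default half the
#'   cohort.
#' @param blacklist Optional blacklist data frame.
#' @param depth_min,frip_min QC thresholds (scaled to the simulated depth by
#'   default).
#' @param contamination,outlier_seed Robust-PCA outlier parameters.
#' @param fdr FDR threshold for opening/closing calls.
#' @param k Number of CV groups.
#' @param lambda_grid,alpha_grid Clock hyperparameter grids (compact
#'   defaults suited to the simulated scale).
#' @return Invisibly, a list with the intermediate objects and output paths.
#' @export
run_pipeline <- function(out_dir, config = fragment_config(),
                         min_samples = NULL, blacklist = NULL,
                         depth_min = 1000, frip_min = 0.1,
                         contamination = 0.1, outlier_seed = 1,
                         fdr = 0.01, k = 5,
                         lambda_grid = exp(seq(log(0.01), log(10),
                                               length.out = 6)),
                         alpha_grid = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_fragments(config)
  if (is.null(min_samples)) {
    min_samples <- max(1L, floor(config$cohort$n_samples / 2))
  }
  consensus <- build_consensus(sim$peak_calls, min_samples, blacklist)
  write_ocr_bed(consensus, file.path(out_dir, "consensus.bed"))
  counts <- count_cut_sites(sim$fragments, consensus)
  write_matrix_tsv(counts, file.path(out_dir, "counts.tsv"), "ocr_id")
  qc <- data.frame(
    sample_id = names(sim$fragments),
    n_alignments = vapply(sim$fragments, nrow, integer(1)),
    frip = vapply(sim$fragments, compute_frip, numeric(1), ocrs = consensus)
  )
  qc <- qc_filter(qc, depth_min = depth_min, frip_min = frip_min)
  norm <- normalize_accessibility(counts[, qc$pass, drop = FALSE],
                                  consensus$length_bp)
  qc$is_outlier <- FALSE
  if (sum(qc$pass) >= 10) {
    out <- remove_outliers(norm$log_normalized, contamination, outlier_seed)
    qc$is_outlier[qc$pass] <- unname(out)
  }
  utils::write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  keep_ids <- qc$sample_id[qc$pass & !qc$is_outlier]
  logm <- norm$log_normalized[, keep_ids, drop = FALSE]
  ages <- sim$samples$age[match(keep_ids, sim$samples$sample_id)]
  corr <- age_correlations(logm, ages, q_threshold = fdr)
  utils::write.table(corr, file.path(out_dir, "age_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- assign_age_groups(ages, k = k,
                             seed = substream_seed(config$seed, "cv"))
  cv <- nested_cv(t(logm), ages, folds, lambda_grid, alpha_grid)
  utils::write.table(cv$predictions, file.path(out_dir,
                                               "cv_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    n_consensus_ocrs = nrow(consensus),
    n_samples_pass = length(keep_ids),
    n_opening = sum(corr$class == "opening"),
    n_closing = sum(corr$class == "closing"),
    cv = cv$aggregate
  ), file.path(out_dir, "summary.json"), digits = NA, auto_unbox = TRUE,
  pretty = TRUE)
  invisible(list(sim = sim, consensus = consensus, counts = counts, qc = qc,
                 age_correlations = corr, cv = cv,
                 files = file.path(out_dir,
                                   c("consensus.bed", "counts.tsv", "qc.tsv",
                                     "age_correlations.tsv",
                                     "cv_predictions.tsv", "summary.json"))))
}
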