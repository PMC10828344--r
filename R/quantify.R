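# Cut-site positions (0-based) of a fragment set: the first covered base and
# the last covered base (end - 1), so both sites are 1-bp positions inside the
# fragment.
fragment_cut_sites <- function(fragments) {
  data.frame(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1L),
    stringsAsFactors = FALSE
  )
}

#' Count Tn5 cut sites over OCRs
#'
#' Each fragment contributes two cut sites (its start and its last covered
#' base); a cut site increments an OCR's count when the 1-bp site lies within
#' the OCR, so a fragment contributes 0, 1 or 2 counts. Fragments on
#' chromosomes absent from the OCR set are skipped (a message reports how
#' many).
#'
#' @param fragments Named list of per-sample fragment data frames (`chrom`,
#'   `start`, `end`; Tn5-shift-corrected).
#' @param ocrs OCR data frame with `id` column.
#' @return Integer matrix of cut-site counts, OCRs x samples.
#' @export
count_cut_sites <- function(fragments, ocrs) {
  ocr_gr <- bed_to_gr(ocrs)
  known <- unique(ocrs$chrom)
  counts <- matrix(0L, nrow = nrow(ocrs), ncol = length(fragments),
                   dimnames = list(ocrs$id, names(fragments)))
  skipped <- 0L
  for (j in seq_along(fragments)) {
    fr <- fragments[[j]]
    validate_intervals(fr, paste0("fragments for sample ", j))
    off <- !(fr$chrom %in% known)
    skipped <- skipped + sum(off)
    sites <- fragment_cut_sites(fr[!off, , drop = FALSE])
    site_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, ocr_gr))
    counts[, j] <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(ocrs))
  }
  if (skipped > 0) {
    message(skipped, " fragments on chromosomes absent from the OCR set were skipped")
  }
  counts
}

#' Normalize cut-site counts to densities per million reads-in-peaks
#'
#' Counts are divided by OCR length in kilobases (density) and then by the
#' sample's total reads-in-peaks in millions, so for every sample the
#' length-weighted sum of normalized values is exactly 1e6. The log matrix is
#' the natural log of the normalized values plus a pseudocount.
#'
#' @param counts OCR x sample count matrix.
#' @param ocr_lengths_bp OCR lengths in bp, aligned with rows of `counts`.
#' @param pseudocount Added before taking logs (default 1 on the normalized
#'   scale).
#' @return List with matrices `normalized` and `log_normalized`.
#' @export
normalize_accessibility <- function(counts, ocr_lengths_bp, pseudocount = 1) {
  stopifnot(length(ocr_lengths_bp) == nrow(counts), all(ocr_lengths_bp > 0))
  rip <- colSums(counts)
  if (any(rip == 0)) {
    stop("all-zero count column for sample(s): ",
         paste(colnames(counts)[rip == 0], collapse = ", "))
  }
  density <- counts / (ocr_lengths_bp / 1000)
  normalized <- sweep(density, 2, rip / 1e6, "/")
  list(normalized = normalized,
       log_normalized = log(normalized + pseudocount))
}

#' Fraction of cut sites in peaks (FRIP)
#'
#' @param fragments A single sample's fragment data frame.
#' @param ocrs OCR data frame.
#' @return The fraction of the sample's Tn5 cut sites that fall within any
#'   OCR, in `[0, 1]`.
#' @export
compute_frip <- function(fragments, ocrs) {
  if (!nrow(fragments)) stop("cannot compute FRIP with zero fragments")
  sites <- fragment_cut_sites(fragments)
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L)
  )
  mean(suppressWarnings(IRanges::overlapsAny(site_gr, bed_to_gr(ocrs))))
}

#' Depth and FRIP quality filter
#'
#' A sample fails when it has fewer than `depth_min` good-quality alignments
#' or a FRIP below `frip_min`; boundary values pass. Defaults are the blood
#' cohort thresholds (11 million alignments, FRIP 0.18).
#'
#' @param sample_qc Data frame with columns `sample_id`, `n_alignments`,
#'   `frip`.
#' @param depth_min Minimum alignment count (inclusive).
#' @param frip_min Minimum FRIP (inclusive).
#' @return `sample_qc` with logical columns `pass_depth`, `pass_frip`,
#'   `pass`.
#' @export
qc_filter <- function(sample_qc, depth_min = 11e6, frip_min = 0.18) {
  sample_qc$pass_depth <- sample_qc$n_alignments >= depth_min
  sample_qc$pass_frip <- sample_qc$frip >= frip_min
  sample_qc$pass <- sample_qc$pass_depth & sample_qc$pass_frip
  sample_qc
}

#' Flag outlier samples with a robust ellipse on PC1/PC2
#'
#' Samples are projected onto the first two principal components of the
#' log-normalized matrix (features centered, not scaled), a
#' minimum-covariance-determinant ellipse is fitted to the scores, and
#' samples whose robust Mahalanobis distance exceeds the
#' `(1 - contamination)` empirical quantile are flagged, so the flagged
#' fraction is approximately `contamination`. Degenerate score clouds (zero
#' spread, e.g. duplicated samples) flag nothing.
#'
#' @param log_normalized OCR x sample matrix of log normalized accessibility.
#' @param contamination Expected outlier fraction, in (0, 0.5).
#' @param seed Integer seed for the robust-covariance subsampling (required).
#' @return Named logical vector, `TRUE` for flagged samples.
#' @export
remove_outliers <- function(log_normalized, contamination = 0.1, seed) {
  if (missing(seed)) stop("a seed for the robust covariance fit is required")
  n <- ncol(log_normalized)
  if (n < 10) stop("at least 10 samples are required for outlier detection")
  if (!(contamination > 0 && contamination < 0.5)) {
    stop("contamination must lie in (0, 0.5)")
  }
  pc <- stats::prcomp(t(log_normalized), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (any(apply(scores, 2, stats::sd) < 1e-10)) {
    return(stats::setNames(rep(FALSE, n), colnames(log_normalized)))
  }
  rob <- tryCatch(
    with_seed(seed, MASS::cov.rob(scores, method = "mcd")),
    error = function(e) {
      stop("robust covariance fit failed (too few samples?): ",
           conditionMessage(e))
    }
  )
  d <- stats::mahalanobis(scores, rob$center, rob$cov)
  flag <- d > stats::quantile(d, 1 - contamination, type = 1)
  stats::setNames(as.vector(flag), colnames(log_normalized))
}
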