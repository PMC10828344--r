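#' Union-merge peak sets
#'
#' Computes the minimal set of disjoint intervals covering the union of all
#' input peak sets. Overlapping and book-ended intervals (one ending where the
#' next starts, in half-open coordinates) are merged. All coordinates are
#' 0-based half-open (BED convention).
#'
#' @param peak_sets A list of interval data frames (`chrom`, `start`, `end`),
#'   or a single data frame.
#' @return A sorted data frame of disjoint intervals.
#' @examples
#' merge_union(list(
#'   data.frame(chrom = "chr1", start = 0, end = 10),
#'   data.frame(chrom = "chr1", start = 5, end = 12)
#' ))
#' @export
merge_union <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (!length(peak_sets)) stop("no peak sets supplied")
  for (i in seq_along(peak_sets)) {
    validate_intervals(peak_sets[[i]], paste0("peak set ", i))
  }
  all <- do.call(rbind, lapply(peak_sets, function(x) {
    x[, c("chrom", "start", "end")]
  }))
  merged <- GenomicRanges::reduce(bed_to_gr(all))
  sort_intervals(gr_to_bed(merged))
}

#' Regions reliably called across samples
#'
#' Returns the maximal sub-regions where at least `min_samples` of the input
#' peak sets overlap simultaneously (multi-way intersection depth). Matches
#' the consensus-building step that keeps regions called as a peak in a
#' minimum number of samples (default 50 in the blood cohort workflow).
#'
#' @param peak_sets List of interval data frames, one per sample.
#' @param min_samples Minimum number of sets that must cover a base.
#' @return A sorted data frame of intervals with coverage depth >=
#'   `min_samples`.
#' @export
reliably_called_regions <- function(peak_sets, min_samples) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  min_samples <- as.integer(min_samples)
  if (min_samples < 1L) stop("min_samples must be >= 1")
  if (min_samples > length(peak_sets)) {
    stop("min_samples (", min_samples, ") exceeds the number of peak sets (",
         length(peak_sets), ")")
  }
  grl <- lapply(seq_along(peak_sets), function(i) {
    validate_intervals(peak_sets[[i]], paste0("peak set ", i))
    GenomicRanges::reduce(bed_to_gr(peak_sets[[i]]))
  })
  if (sum(vapply(grl, length, integer(1))) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cov <- GenomicRanges::coverage(suppressWarnings(do.call(c, grl)))
  sl <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
  n <- S4Vectors::elementNROWS(sl)
  if (sum(n) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(rep(names(sl), n), unlist(sl, use.names = FALSE))
  sort_intervals(gr_to_bed(gr))
}

#' Build a consensus OCR set
#'
#' Computes the union of per-sample peak sets, keeps union peaks that overlap
#' (by at least one base) a region reliably called in `min_samples` or more
#' samples, and removes peaks overlapping any blacklist region. OCR ids are
#' `chrom:start-end` in BED coordinates.
#'
#' @param peak_sets List of per-sample interval data frames.
#' @param min_samples Reliability threshold (number of samples; the blood
#'   cohort workflow used 50).
#' @param blacklist Optional data frame of regions to exclude (e.g. the
#'   ENCODE blacklist); `NULL` or zero rows for none.
#' @return Data frame with columns `chrom`, `start`, `end`, `id`,
#'   `length_bp`, `annotation` (initially `NA`).
#' @export
build_consensus <- function(peak_sets, min_samples, blacklist = NULL) {
  union <- merge_union(peak_sets)
  reliable <- reliably_called_regions(peak_sets, min_samples)
  keep <- suppressWarnings(
    IRanges::overlapsAny(bed_to_gr(union), bed_to_gr(reliable))
  )
  union <- union[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist)) {
    validate_intervals(blacklist, "blacklist")
    drop <- suppressWarnings(
      IRanges::overlapsAny(bed_to_gr(union), bed_to_gr(blacklist))
    )
    union <- union[!drop, , drop = FALSE]
  }
  if (!nrow(union)) warning("consensus OCR set is empty")
  ocrs <- data.frame(
    chrom = union$chrom, start = union$start, end = union$end,
    id = sprintf("%s:%d-%d", union$chrom, union$start, union$end),
    length_bp = union$end - union$start,
    annotation = rep(NA_character_, nrow(union)),
    stringsAsFactors = FALSE
  )
  rownames(ocrs) <- NULL
  ocrs
}

# Nearest gene by TSS distance from the OCR midpoint; ties broken by the
# lexicographically smallest gene symbol. Returns a character vector aligned
# with `ocrs` (NA when the chromosome carries no TSS).
nearest_tss_gene <- function(ocrs, genes) {
  out <- rep(NA_character_, nrow(ocrs))
  mid <- floor((ocrs$start + ocrs$end) / 2)
  for (ch in unique(ocrs$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    io <- which(ocrs$chrom == ch)
    if (!nrow(g)) next
    # one record per TSS position, keeping the smallest symbol, so the
    # left/right candidate comparison below resolves all ties
    g <- g[order(g$tss, g$gene), , drop = FALSE]
    g <- g[!duplicated(g$tss), , drop = FALSE]
    pos <- g$tss
    idx <- findInterval(mid[io], pos)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(pos))
    dl <- abs(mid[io] - pos[left])
    dr <- abs(mid[io] - pos[right])
    dl[idx < 1L] <- Inf
    pick <- ifelse(dl < dr, left,
                   ifelse(dr < dl, right,
                          ifelse(g$gene[left] <= g$gene[right], left, right)))
    out[io] <- g$gene[pick]
  }
  out
}

#' Annotate OCRs as promoters and/or enhancers
#'
#' An OCR is a promoter when it intersects the closed window
#' `[tss - promoter_window_bp, tss + promoter_window_bp]` around any TSS, and
#' an enhancer when it intersects any enhancer region. The four resulting
#' classes (`promoter`, `enhancer`, `promoter_and_enhancer`, `unannotated`)
#' are mutually exclusive and exhaustive. OCRs whose annotation includes
#' promoter are linked to the nearest gene by TSS distance.
#'
#' @param ocrs OCR data frame from [build_consensus()].
#' @param genes TSS table (`gene`, `chrom`, `tss`, `strand`), 0-based
#'   positions.
#' @param enhancers Data frame of enhancer intervals (`chrom`, `start`,
#'   `end`); extra columns ignored.
#' @param promoter_window_bp Half-width of the promoter window (default 1000).
#' @return `ocrs` with `annotation` and `linked_gene` columns filled in.
#' @export
annotate_ocrs <- function(ocrs, genes, enhancers, promoter_window_bp = 1000) {
  stopifnot(promoter_window_bp > 0)
  ocr_gr <- bed_to_gr(ocrs)
  is_prom <- rep(FALSE, nrow(ocrs))
  if (nrow(genes)) {
    prom <- data.frame(
      chrom = genes$chrom,
      start = pmax(genes$tss - promoter_window_bp, 0),
      end = genes$tss + promoter_window_bp + 1
    )
    is_prom <- suppressWarnings(IRanges::overlapsAny(ocr_gr, bed_to_gr(prom)))
  }
  is_enh <- rep(FALSE, nrow(ocrs))
  if (!is.null(enhancers) && nrow(enhancers)) {
    is_enh <- suppressWarnings(IRanges::overlapsAny(ocr_gr, bed_to_gr(enhancers)))
  }
  ocrs$annotation <- ifelse(
    is_prom & is_enh, "promoter_and_enhancer",
    ifelse(is_prom, "promoter", ifelse(is_enh, "enhancer", "unannotated"))
  )
  ocrs$linked_gene <- NA_character_
  if (any(is_prom)) {
    ocrs$linked_gene[is_prom] <- nearest_tss_gene(
      ocrs[is_prom, , drop = FALSE], genes
    )
  }
  ocrs
}

#' Link OCRs to genes
#'
#' `nearest` mode assigns each OCR the single gene whose TSS is closest to the
#' OCR midpoint (ties to the lexicographically smallest symbol). `link_table`
#' mode returns all genes whose enhancer-link regions overlap the OCR (zero to
#' many per OCR), mirroring link resources such as PEREGRINE.
#'
#' @param ocrs OCR data frame with an `id` column.
#' @param genes TSS table.
#' @param links Enhancer-link table (`chrom`, `start`, `end`, `gene`), used in
#'   `link_table` mode.
#' @param mode `"nearest"` or `"link_table"`.
#' @return Data frame with columns `ocr_id`, `gene`.
#' @export
link_genes <- function(ocrs, genes = NULL, links = NULL,
                       mode = c("nearest", "link_table")) {
  mode <- match.arg(mode)
  if (mode == "nearest") {
    if (is.null(genes) || !nrow(genes)) stop("empty gene annotation")
    data.frame(ocr_id = ocrs$id,
               gene = nearest_tss_gene(ocrs, genes),
               stringsAsFactors = FALSE)
  } else {
    if (is.null(links) || !nrow(links)) {
      return(data.frame(ocr_id = character(), gene = character()))
    }
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(bed_to_gr(ocrs), bed_to_gr(links))
    )
    out <- data.frame(
      ocr_id = ocrs$id[S4Vectors::queryHits(hits)],
      gene = links$gene[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
    unique(out)
  }
}
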