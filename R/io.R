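#' Read a BED3/BED6 file
#'
#' Reads tab-separated BED intervals (0-based half-open, no header). Columns
#' beyond the third are kept as `name`, `score`, `strand` when present.
#'
#' @param path Path to a BED file (plain text, optionally gzipped).
#' @return A data frame with columns `chrom`, `start`, `end` and, if present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6))]
  validate_intervals(x, basename(path))
  x
}

#' Read a MACS2 narrowPeak file
#'
#' narrowPeak is BED6+4; only the interval columns and the peak name are
#' retained (the summit column is ignored; coordinates are BED half-open).
#'
#' @param path Path to a narrowPeak file.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_narrowpeak <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  x <- x[, seq_len(min(ncol(x), 4)), drop = FALSE]
  names(x) <- c("chrom", "start", "end", "name")[seq_len(ncol(x))]
  validate_intervals(x, basename(path))
  x
}

#' Read a fragment BED file
#'
#' Fragments are expected Tn5-shift-corrected. When `tn5_shift = TRUE` the
#' conventional (+4, -5) correction is applied to (start, end) of raw
#' fragments.
#'
#' @param path Path to a BED3 fragment file.
#' @param tn5_shift Apply the +4/-5 Tn5 offset to raw fragment coordinates.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_fragments <- function(path, tn5_shift = FALSE) {
  x <- read_bed(path)[, c("chrom", "start", "end")]
  if (tn5_shift) {
    x$start <- x$start + 4L
    x$end <- x$end - 5L
    x <- x[x$end > x$start, , drop = FALSE]
  }
  validate_intervals(x, basename(path))
  x
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene`, `chrom`, `tss`, `strand`; `tss`
#' is the 0-based position of the (strand-resolved) transcription start site.
#'
#' @param path Path to the TSV file.
#' @return Data frame with those columns.
#' @export
read_tss_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(x))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Read an enhancer-gene link table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `gene`,
#' `tissue` describing enhancer regions and the genes they are linked to
#' (one row per link; an enhancer may link several genes and vice versa).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those columns.
#' @export
read_enhancer_links <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "tissue")
  if (!all(need %in% names(x))) {
    stop("enhancer link table must have columns: ",
         paste(need, collapse = ", "))
  }
  validate_intervals(x, basename(path))
  x
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature identifiers, remaining columns one sample each.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus OCR set to BED
#'
#' Emits chrom, start, end, id and (when present) the annotation class.
#'
#' @param ocrs OCR data frame as returned by [build_consensus()] /
#'   [annotate_ocrs()].
#' @param path Output path.
#' @export
write_ocr_bed <- function(ocrs, path) {
  cols <- intersect(c("chrom", "start", "end", "id", "annotation"),
                    names(ocrs))
  utils::write.table(ocrs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: term, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}
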