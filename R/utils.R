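#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the previous
#' RNG state afterwards, so seeded operations never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-layer sub-seed derived from a base seed and a stream name,
# kept below 2^31 so it is always a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Validate a BED-style interval data frame (0-based half-open coordinates).
# `what` names the set in error messages; row names / `name` column are used
# to identify offending features.
validate_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(what, " must be a data frame with columns chrom, start, end")
  }
  bad <- which(!(x$end > x$start) | x$start < 0)
  if (length(bad)) {
    id <- if ("name" %in% names(x)) x$name[bad[1]] else paste0("row ", bad[1])
    stop("malformed interval in ", what, " (end <= start or start < 0): ", id)
  }
  invisible(x)
}

# BED (0-based half-open) <-> GRanges (1-based closed) conversion.
bed_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Sort a BED data frame by (chrom lexicographic, start, end).
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}
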