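#' Genome-wide age correlations
#'
#' Computes, per feature, the Spearman rank correlation with age, a two-sided
#' p-value from the t approximation, Benjamini-Hochberg q-values over all
#' features of the matrix, and the resulting class: `opening` (r > 0,
#' q < threshold), `closing` (r < 0, q < threshold), otherwise `stable`.
#' Constant features get r = 0, p = 1, class `stable` and are flagged.
#'
#' @param mat Feature x sample matrix.
#' @param ages Sample ages in years, aligned with columns.
#' @param q_threshold FDR threshold for calling opening/closing (default
#'   0.01).
#' @param modality Label recorded in the output (`"atac"`, `"rna"`,
#'   `"methylation"`, ...).
#' @return Data frame with columns `feature_id`, `modality`, `spearman_r`,
#'   `p_value`, `q_value`, `class`, `constant`.
#' @export
age_correlations <- function(mat, ages, q_threshold = 0.01,
                             modality = "atac") {
  n <- ncol(mat)
  stopifnot(n >= 3, length(ages) == n, all(is.finite(ages)))
  rmat <- t(apply(mat, 1, rank))
  ra <- rank(ages)
  r <- suppressWarnings(as.vector(stats::cor(t(rmat), ra)))
  constant <- !is.finite(r)
  r[constant] <- 0
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- Inf
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[constant] <- 1
  q <- stats::p.adjust(p, method = "BH")
  cls <- ifelse(q < q_threshold & r > 0, "opening",
                ifelse(q < q_threshold & r < 0, "closing", "stable"))
  data.frame(
    feature_id = rownames(mat), modality = modality,
    spearman_r = r, p_value = p, q_value = q, class = cls,
    constant = constant, stringsAsFactors = FALSE
  )
}

#' Enrichment of an annotation class among opening/closing OCRs
#'
#' Builds the 2x2 table of (in the direction class vs background) against
#' (carrying the annotation vs not) and applies Fisher's exact test
#' (two-sided). The background is every OCR not in the direction class. The
#' reported odds ratio is the sample cross-product ratio (infinite when a
#' zero cell makes it so, with a flag).
#'
#' @param table Age-correlation table from [age_correlations()].
#' @param ocrs Annotated OCR data frame (`id`, `annotation`).
#' @param direction `"opening"` or `"closing"`.
#' @param annotation Annotation element tested (default `"enhancer"`).
#' @param include_dual Count `promoter_and_enhancer` OCRs as carrying either
#'   element (default TRUE).
#' @return List with `odds_ratio`, `log_odds`, `p_value`, `table`,
#'   `degenerate`.
#' @export
annotation_enrichment <- function(table, ocrs, direction,
                                  annotation = "enhancer",
                                  include_dual = TRUE) {
  stopifnot(direction %in% c("opening", "closing"))
  ann <- ocrs$annotation[match(table$feature_id, ocrs$id)]
  carries <- ann == annotation
  if (include_dual) carries <- carries | ann == "promoter_and_enhancer"
  in_class <- table$class == direction
  if (!any(in_class)) stop("no OCRs in class ", direction)
  m <- matrix(c(
    sum(in_class & carries), sum(in_class & !carries),
    sum(!in_class & carries), sum(!in_class & !carries)
  ), nrow = 2, byrow = TRUE)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  p <- stats::fisher.test(m)$p.value
  list(odds_ratio = or, log_odds = log(or), p_value = p, table = m,
       degenerate = !is.finite(or) || or == 0)
}

#' One-sided two-sample Kolmogorov-Smirnov shift test
#'
#' Tests whether `target` values are stochastically greater (direction
#' `"greater"`) or smaller (`"less"`) than `background`. D is the maximal
#' signed ECDF difference in the stated direction; the p-value uses the
#' asymptotic one-sided formula `exp(-2 n_eff D^2)` with
#' `n_eff = n1 n2 / (n1 + n2)`.
#'
#' @param target_values,background_values Numeric samples (each n >= 2).
#' @param direction `"greater"` or `"less"` (sense of the shift of `target`).
#' @return List with `D`, `p_value`, `direction`, `n_target`, `n_background`.
#' @export
ks_shift <- function(target_values, background_values,
                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  n1 <- length(target_values)
  n2 <- length(background_values)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values")
  grid <- sort(unique(c(target_values, background_values)))
  ft <- stats::ecdf(target_values)(grid)
  fb <- stats::ecdf(background_values)(grid)
  d <- if (direction == "greater") max(fb - ft) else max(ft - fb)
  d <- max(d, 0)
  n_eff <- n1 * n2 / (n1 + n2)
  list(D = d, p_value = min(1, exp(-2 * n_eff * d^2)),
       direction = direction, n_target = n1, n_background = n2)
}

#' Assign CpGs to the OCRs containing them
#'
#' A CpG at 0-based position p is assigned to the OCR with
#' `start <= p < end`; CpGs outside all OCRs get `NA`.
#'
#' @param cpgs Data frame with `cpg_id`, `chrom`, `pos` (0-based 1-bp
#'   positions).
#' @param ocrs OCR data frame with `id`.
#' @return Data frame `cpg_id`, `ocr_id` (`NA` when unassigned).
#' @export
link_cpgs_to_ocrs <- function(cpgs, ocrs) {
  cpg_gr <- GenomicRanges::GRanges(
    cpgs$chrom, IRanges::IRanges(cpgs$pos + 1L, width = 1L)
  )
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(cpg_gr, bed_to_gr(ocrs), select = "first")
  )
  data.frame(cpg_id = cpgs$cpg_id,
             ocr_id = ifelse(is.na(hit), NA_character_, ocrs$id[hit]),
             stringsAsFactors = FALSE)
}

#' Correlation between two modalities' age-correlation profiles
#'
#' Pearson correlation between the per-feature age correlations of two
#' modalities, evaluated over linked feature pairs (e.g. OCR-gene or
#' CpG-gene links). When one feature links to several partners each link
#' counts as one observation.
#'
#' @param table_a,table_b Age-correlation tables ([age_correlations()]).
#' @param links Data frame with columns `feature_a` (ids in `table_a`),
#'   `feature_b` (ids in `table_b`), and optionally `region_class`.
#' @param region_class Optional filter on `links$region_class`.
#' @return List with `r`, `n_pairs`, `region_class`.
#' @export
correlation_of_correlations <- function(table_a, table_b, links,
                                        region_class = NULL) {
  if (!is.null(region_class)) {
    links <- links[links$region_class %in% region_class, , drop = FALSE]
  }
  ra <- table_a$spearman_r[match(links$feature_a, table_a$feature_id)]
  rb <- table_b$spearman_r[match(links$feature_b, table_b$feature_id)]
  ok <- is.finite(ra) & is.finite(rb)
  if (sum(ok) < 3) stop("fewer than 3 linked pairs with finite correlations")
  list(r = stats::cor(ra[ok], rb[ok]), n_pairs = sum(ok),
       region_class = if (is.null(region_class)) NA_character_ else region_class)
}
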