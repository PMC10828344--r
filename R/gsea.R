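#' Build a ranked gene list from OCR accessibility
#'
#' Implements the OCR-to-gene ranking used for accessibility GSEA:
#' (1) OCR-gene pairs without a linked gene are dropped; (2) pairs whose gene
#' is absent from the expression matrix are dropped; (3) when a gene is
#' linked to several OCRs, `best_pair` mode keeps the pair with the largest
#' absolute Spearman correlation between accessibility and expression across
#' the samples shared by both assays, while `promoter_only` mode keeps only
#' promoter pairs; (4) the gene score is the Spearman correlation between the
#' kept OCR's accessibility and age, and genes are returned sorted by
#' descending score.
#'
#' @param links Data frame with `ocr_id`, `gene`, and (for `promoter_only`)
#'   an `annotation` column.
#' @param atac_matrix OCR x sample accessibility matrix (log scale).
#' @param rna_matrix Gene x sample expression matrix.
#' @param ages Ages aligned with `colnames(atac_matrix)`.
#' @param mode `"best_pair"` or `"promoter_only"`.
#' @return Data frame `gene`, `ocr_id`, `score`, sorted by descending score.
#' @export
build_ranked_list <- function(links, atac_matrix, rna_matrix, ages,
                              mode = c("best_pair", "promoter_only")) {
  mode <- match.arg(mode)
  common <- intersect(colnames(atac_matrix), colnames(rna_matrix))
  if (!length(common)) stop("no samples shared between ATAC and RNA matrices")
  links <- links[!is.na(links$gene) & links$gene %in% rownames(rna_matrix) &
                   links$ocr_id %in% rownames(atac_matrix), , drop = FALSE]
  if (mode == "promoter_only") {
    if (!"annotation" %in% names(links)) {
      stop("promoter_only mode requires an annotation column in links")
    }
    links <- links[links$annotation %in%
                     c("promoter", "promoter_and_enhancer"), , drop = FALSE]
  }
  if (!nrow(links)) stop("no usable OCR-gene links")
  ae_cor <- vapply(seq_len(nrow(links)), function(i) {
    suppressWarnings(stats::cor(atac_matrix[links$ocr_id[i], common],
                                rna_matrix[links$gene[i], common],
                                method = "spearman"))
  }, numeric(1))
  ae_cor[!is.finite(ae_cor)] <- 0
  ord <- order(links$gene, -abs(ae_cor))
  links <- links[ord, , drop = FALSE]
  keep <- !duplicated(links$gene)
  kept <- links[keep, , drop = FALSE]
  score <- vapply(kept$ocr_id, function(o) {
    suppressWarnings(stats::cor(atac_matrix[o, ], ages, method = "spearman"))
  }, numeric(1))
  score[!is.finite(score)] <- 0
  out <- data.frame(gene = kept$gene, ocr_id = kept$ocr_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted KS running sum for positions `idx` (sorted hit positions in a list
# of length N) with weights |score|^p; returns the signed extremum. Candidate
# extrema occur at each hit and immediately before it.
es_from_positions <- function(idx, w, N) {
  k <- length(idx)
  if (k == 0) return(NA_real_)
  if (k == N) return(1)
  hw <- w[idx]
  sw <- sum(hw)
  if (sw == 0) hw <- rep(1 / k, k) else hw <- hw / sw
  ch <- cumsum(hw)
  miss <- 1 / (N - k)
  at_hit <- ch - (idx - seq_len(k)) * miss
  before_hit <- c(0, ch[-k]) - (idx - seq_len(k)) * miss
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Preranked GSEA enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov running sum: walking down the ranked
#' list, hits increment by `|score|^p / sum_hits |score|^p` and misses
#' decrement by `1 / (N - N_hits)`; the enrichment score is the signed
#' extremum of the running sum.
#'
#' @param ranked Data frame with `gene` and `score` (any order; sorted
#'   internally by descending score), or a named numeric vector of scores.
#' @param gene_set Character vector of member genes.
#' @param weight_p Score weighting exponent (default 1).
#' @return List with `es`, `running` (the full running sum), `hits` (logical
#'   per position). `es` is `NA` with a warning when the set does not
#'   intersect the list.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  rl <- as_ranked_vector(ranked)
  s <- rl$score
  genes <- rl$gene
  N <- length(s)
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0) {
    warning("gene set does not intersect the ranked list")
    return(list(es = NA_real_, running = rep(NA_real_, N), hits = hit))
  }
  w <- abs(s)^weight_p
  if (k == N) {
    sw <- sum(w)
    running <- if (sw == 0) cumsum(rep(1 / N, N)) else cumsum(w / sw)
    return(list(es = 1, running = running, hits = hit))
  }
  sw <- sum(w[hit])
  inc <- if (sw == 0) rep(1 / k, N) else w / sw
  step <- ifelse(hit, inc, -1 / (N - k))
  running <- cumsum(step)
  list(es = running[which.max(abs(running))], running = running, hits = hit)
}

as_ranked_vector <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene", "score") %in% names(ranked)))
    gene <- ranked$gene
    score <- ranked$score
  } else {
    gene <- names(ranked)
    score <- as.numeric(ranked)
  }
  if (anyDuplicated(gene)) stop("duplicate genes in ranked list")
  if (any(!is.finite(score))) stop("non-finite scores in ranked list")
  ord <- order(-score)
  list(gene = gene[ord], score = score[ord])
}

#' Preranked GSEA with permutation-based NES
#'
#' For each gene set, the enrichment score is compared with a null built from
#' `n_perm` random gene-label permutations at the same set size. NES is the
#' observed ES divided by the mean absolute null ES of matching sign; the
#' nominal p-value is the fraction of same-sign null scores at least as
#' extreme, and q-values are Benjamini-Hochberg across terms. Sets that do
#' not intersect the ranked list are skipped with a message.
#'
#' @param ranked Ranked list (data frame `gene`,`score` or named vector).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param weight_p Score weighting exponent.
#' @param seed Integer seed making the permutations reproducible.
#' @return Data frame with `term_id`, `term_size`, `es`, `nes`, `p_value`,
#'   `q_value`, `leading_edge` (comma-separated genes).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, weight_p = 1,
                           seed = 1) {
  stopifnot(n_perm >= 100)
  rl <- as_ranked_vector(ranked)
  genes <- rl$gene
  s <- rl$score
  N <- length(genes)
  w <- abs(s)^weight_p
  sizes <- vapply(gene_sets, function(g) sum(genes %in% g), integer(1))
  usable <- sizes > 0
  if (any(!usable)) {
    message(sum(!usable), " gene set(s) skipped: no overlap with ranked list")
  }
  uniq_sizes <- sort(unique(sizes[usable & sizes < N]))
  nulls <- with_seed(seed, {
    out <- list()
    for (k in uniq_sizes) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sort(sample.int(N, k)), w, N)
      }, numeric(1))
    }
    out
  })
  res <- lapply(names(gene_sets)[usable], function(term) {
    k <- sizes[[term]]
    esr <- enrichment_score(data.frame(gene = genes, score = s),
                            gene_sets[[term]], weight_p)
    es <- esr$es
    if (k >= N) {
      return(data.frame(term_id = term, term_size = k, es = es, nes = NA_real_,
                        p_value = NA_real_, leading_edge = NA_character_,
                        stringsAsFactors = FALSE))
    }
    null <- nulls[[as.character(k)]]
    if (es == 0) {
      same <- numeric(0)
      nes <- 0
      p <- 1
    } else {
      same <- null[sign(null) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- if (length(same)) mean(abs(same) >= abs(es)) else 0
    }
    peak <- which.max(abs(esr$running))
    le <- if (es >= 0) {
      genes[seq_len(peak)][esr$hits[seq_len(peak)]]
    } else {
      genes[peak:N][esr$hits[peak:N]]
    }
    data.frame(term_id = term, term_size = k, es = es, nes = nes,
               p_value = p, leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[, c("term_id", "term_size", "es", "nes", "p_value", "q_value",
          "leading_edge")]
}
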