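# Brute-force oracles used across the suite. All are deliberately naive
# (per-base arrays, explicit enumeration, normal equations) and independent
# of the package's implementation paths.

# Per-base union of interval sets over a small coordinate range.
oracle_union <- function(sets, max_bp = 20000) {
  chroms <- unique(unlist(lapply(sets, function(s) s$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    covered <- logical(max_bp)
    for (s in sets) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sc))) {
        covered[(sc$start[i] + 1):sc$end[i]] <- TRUE
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-base coverage depth >= min_samples (each set counted once per base).
oracle_depth_regions <- function(sets, min_samples, max_bp = 20000) {
  chroms <- unique(unlist(lapply(sets, function(s) s$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    depth <- integer(max_bp)
    for (s in sets) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      covered <- logical(max_bp)
      for (i in seq_len(nrow(sc))) {
        covered[(sc$start[i] + 1):sc$end[i]] <- TRUE
      }
      depth <- depth + covered
    }
    ok <- depth >= min_samples
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random small interval sets on 1-2 chromosomes within 10 kb.
random_interval_sets <- function(n_sets, max_intervals = 6, max_bp = 10000) {
  lapply(seq_len(n_sets), function(i) {
    k <- sample.int(max_intervals, 1)
    ch <- sample(c("chr1", "chr2"), k, replace = TRUE)
    st <- sample.int(max_bp - 200, k)
    w <- sample.int(150, k) + 10
    data.frame(chrom = ch, start = st, end = st + w)
  })
}

bed_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Membership oracle: count of 1-bp positions inside any interval.
oracle_sites_in <- function(pos_df, intervals) {
  vapply(seq_len(nrow(pos_df)), function(i) {
    any(intervals$chrom == pos_df$chrom[i] &
          intervals$start <= pos_df$pos[i] &
          pos_df$pos[i] < intervals$end)
  }, logical(1))
}

# Prefix-sum GSEA enrichment-score oracle.
oracle_es <- function(genes, scores, set, p = 1) {
  ord <- order(-scores)
  genes <- genes[ord]
  scores <- scores[ord]
  hit <- genes %in% set
  N <- length(genes)
  k <- sum(hit)
  w <- abs(scores)^p
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / sum(w[hit]) else -1 / (N - k)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table.
oracle_fisher_p <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- vapply(support, function(a) {
    stats::dhyper(a, cs[1], cs[2], rs[1])
  }, numeric(1))
  p_obs <- stats::dhyper(m[1, 1], cs[1], cs[2], rs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form OLS via normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# One-sided two-sample KS statistic by ECDF enumeration on the pooled grid.
oracle_ks_d <- function(target, background, direction) {
  grid <- sort(unique(c(target, background)))
  ft <- vapply(grid, function(g) mean(target <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(background <= g), numeric(1))
  if (direction == "greater") max(0, max(fb - ft)) else max(0, max(ft - fb))
}

# Brute-force BH step-up set at level q.
oracle_bh_reject <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  rej <- logical(n)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
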