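#' Synthetic cohort configuration
#'
#' Default parameters describe a blood-cohort-like study at desk scale:
#' ages uniform on 20-74 years, PBMC cell fractions drifting with age (the NK
#' slope is calibrated so the NK-age Pearson correlation is about 0.3 at
#' n = 150), a small fraction of OCRs carrying cell-intrinsic opening or
#' closing effects in two magnitude tiers, expression age-effects coupled to
#' promoter/enhancer accessibility effects (target couplings about
#' 0.32 / 0.25), methylation age-effects anti-coupled to enhancer
#' accessibility (about -0.20) and essentially uncoupled to expression, and
#' negative-binomial cut-site counts with log-normal library sizes.
#'
#' @param n_samples,n_ocrs,n_genes,n_cpgs Cohort dimensions.
#' @param age_range Age range in years.
#' @param cell_populations Data frame with `population`, `baseline`
#'   (fractions summing to 1) and `slope_per_year` (latent logistic-normal
#'   drift per year of age).
#' @param frac_opening,frac_closing Fractions of OCRs with planted
#'   cell-intrinsic age effects.
#' @param effect_strong,effect_weak Planted log-accessibility slopes per age
#'   standard deviation for the two magnitude tiers.
#' @param background_effect_sd Spread of the small background effects of
#'   unplanted OCRs.
#' @param frac_promoter,frac_enhancer,frac_dual OCR annotation class
#'   proportions (remainder unannotated).
#' @param rho_promoter,rho_enhancer Coupling between accessibility and
#'   expression age effects at promoters / enhancers.
#' @param rho_meth_acc_enhancer,rho_meth_acc_promoter Coupling between CpG
#'   methylation and host-OCR accessibility age effects.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion mu^2).
#' @param libsize_log_sd Log-sd of per-sample reads-in-peaks.
#' @param mean_reads_in_peaks Expected reads-in-peaks per sample.
#' @param composition_sd Logistic-normal sd of cell fractions.
#' @param flow_noise_sd Flow-cytometry gating noise added to the measured
#'   fractions in the sample table (the truth table keeps the exact ones).
#' @param celltype_profile_sd Per-cell-type log-accessibility deviation sd.
#' @param sex_effect_sd Per-OCR additive sex offset sd (log scale).
#' @param expr_effect_sd,expr_noise_sd Gene age-effect and residual sds (log
#'   expression).
#' @param meth_effect_sd,meth_noise_sd CpG age-effect and residual sds
#'   (logit-beta latent scale).
#' @param frac_cpg_in_ocr Fraction of CpGs placed inside OCRs.
#' @param condition_frac Fraction of samples carrying the condition label.
#' @param condition_effect_years Accessibility shift of condition samples,
#'   expressed as years of aging along the planted age axis.
#' @param seed Base seed; each data layer draws from a named substream.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_samples = 150, n_ocrs = 5000, n_genes = 2000, n_cpgs = 3000,
    age_range = c(20, 74),
    cell_populations = data.frame(
      population = c("monocytes", "granulocytes", "B", "NK", "CD4T", "CD8T"),
      baseline = c(0.18, 0.03, 0.10, 0.12, 0.38, 0.19),
      slope_per_year = c(0, 0, 0, 0.0052, -0.0005, -0.004),
      stringsAsFactors = FALSE
    ),
    frac_opening = 0.04, frac_closing = 0.04,
    effect_strong = 0.25, effect_weak = 0.10, background_effect_sd = 0.03,
    frac_promoter = 0.241, frac_enhancer = 0.582, frac_dual = 0.05,
    rho_promoter = 0.32, rho_enhancer = 0.25,
    rho_meth_acc_enhancer = -0.20, rho_meth_acc_promoter = -0.05,
    dispersion = 0.05, libsize_log_sd = 0.3, mean_reads_in_peaks = 3e5,
    composition_sd = 0.25, flow_noise_sd = 0.01,
    celltype_profile_sd = 0.7, sex_effect_sd = 0.05,
    expr_effect_sd = 0.15, expr_noise_sd = 0.3,
    meth_effect_sd = 0.15, meth_noise_sd = 0.3, frac_cpg_in_ocr = 0.7,
    condition_frac = 0, condition_effect_years = 0,
    seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_opening, frac_closing, frac_promoter, frac_enhancer,
          frac_dual, frac_cpg_in_ocr, condition_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_opening + frac_closing > 1) {
    stop("frac_opening + frac_closing must be <= 1")
  }
  if (frac_promoter + frac_enhancer + frac_dual > 1) {
    stop("annotation class fractions must sum to <= 1")
  }
  if (abs(sum(cell_populations$baseline) - 1) > 1e-6) {
    stop("baseline cell fractions must sum to 1")
  }
  if (any(abs(c(rho_promoter, rho_enhancer, rho_meth_acc_enhancer,
                rho_meth_acc_promoter)) > 1)) {
    stop("coupling parameters must lie in [-1, 1]")
  }
  if (sum(cell_populations$population %in%
            c("monocytes", "granulocytes", "B", "NK", "CD4T", "CD8T")) !=
        nrow(cell_populations)) {
    stop("unknown cell population labels")
  }
  class(cfg) <- c("cohort_config", "list")
  cfg
}

# Global genomic slot grid shared by OCRs, orphan TSSs and background
# regions: slot i (0-based, round-robin over 4 chromosomes) starts at
# 10000 + floor(i/4)*5000 on chr{(i mod 4)+1}. OCRs occupy at most the first
# 1000 bp of their slot, so slot offsets >= 1100 are guaranteed OCR-free.
slot_coords <- function(i) {
  list(chrom = paste0("chr", (i %% 4L) + 1L),
       base = 10000L + (i %/% 4L) * 5000L)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces the complete multi-omic data bundle the analysis consumes: an
#' annotated OCR set with TSS table and enhancer-gene links, a
#' negative-binomial accessibility count matrix (plus normalized and log
#' forms), expression and methylation matrices with age effects coupled to
#' accessibility as configured, a sample table with age, sex, condition and
#' measured cell fractions, and a truth object recording every planted
#' effect.
#'
#' @param config A [cohort_config()].
#' @return List with elements `ocrs`, `tss`, `enhancer_links`, `counts`,
#'   `normalized`, `log_normalized`, `expression`, `methylation`,
#'   `cpg_table`, `samples`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cp <- config$cell_populations
  n <- config$n_samples
  p <- config$n_ocrs
  mid_age <- mean(config$age_range)
  age_sd <- diff(config$age_range) / sqrt(12)

  ## --- samples: ages, sex, condition, cell composition ------------------
  samples <- with_seed(substream_seed(config$seed, "samples"), {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.73, 0.27))
    condition <- ifelse(stats::runif(n) < config$condition_frac,
                        "case", "control")
    latent <- matrix(rep(log(cp$baseline), each = n), nrow = n) +
      outer(age - mid_age, cp$slope_per_year) +
      matrix(stats::rnorm(n * nrow(cp), 0, config$composition_sd), nrow = n)
    f <- exp(latent) / rowSums(exp(latent))
    colnames(f) <- cp$population
    f_meas <- pmax(f + matrix(stats::rnorm(n * nrow(cp), 0,
                                           config$flow_noise_sd), nrow = n),
                   1e-4)
    colnames(f_meas) <- cp$population
    list(age = age, sex = sex, condition = condition, fractions = f,
         measured = f_meas)
  })
  sample_id <- sprintf("S%03d", seq_len(n))
  f_true <- samples$fractions
  f <- samples$measured
  sample_table <- data.frame(
    sample_id = sample_id, age = samples$age, sex = samples$sex,
    condition = samples$condition,
    monocytes = f[, "monocytes"], granulocytes = f[, "granulocytes"],
    lymphocytes = f[, "B"] + f[, "NK"] + f[, "CD4T"] + f[, "CD8T"],
    T = f[, "CD4T"] + f[, "CD8T"],
    CD4T = f[, "CD4T"], CD8T = f[, "CD8T"],
    B = f[, "B"], NK = f[, "NK"],
    stringsAsFactors = FALSE
  )

  ## --- OCR universe, TSS table, enhancer links --------------------------
  anno <- with_seed(substream_seed(config$seed, "regions"), {
    cls <- sample(
      c("promoter", "enhancer", "promoter_and_enhancer", "unannotated"), p,
      replace = TRUE,
      prob = c(config$frac_promoter, config$frac_enhancer, config$frac_dual,
               1 - config$frac_promoter - config$frac_enhancer -
                 config$frac_dual)
    )
    width <- sample(200:1000, p, replace = TRUE)
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    perm <- sample.int(config$n_genes)
    enh_gene_pick <- sample.int(config$n_genes, p, replace = TRUE)
    off <- sample(50:120, p, replace = TRUE)
    list(cls = cls, width = width, strand = strand, perm = perm,
         enh_gene_pick = enh_gene_pick, off = off)
  })
  sc <- slot_coords(seq_len(p) - 1L)
  ocrs <- data.frame(
    chrom = sc$chrom, start = sc$base, end = sc$base + anno$width,
    stringsAsFactors = FALSE
  )
  ocrs$id <- sprintf("%s:%d-%d", ocrs$chrom, ocrs$start, ocrs$end)
  ocrs$length_bp <- ocrs$end - ocrs$start
  ocrs$annotation <- anno$cls

  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  has_prom <- anno$cls %in% c("promoter", "promoter_and_enhancer")
  prom_idx <- which(has_prom)
  if (length(prom_idx) > config$n_genes) {
    stop("more promoter OCRs than genes; increase n_genes")
  }
  prom_gene <- anno$perm[seq_along(prom_idx)]   # distinct gene per promoter
  ocr_gene <- rep(NA_integer_, p)
  ocr_gene[prom_idx] <- prom_gene
  tss_pos <- rep(NA_integer_, config$n_genes)
  tss_chrom <- rep(NA_character_, config$n_genes)
  tss_pos[prom_gene] <- floor((ocrs$start[prom_idx] + ocrs$end[prom_idx]) / 2)
  tss_chrom[prom_gene] <- ocrs$chrom[prom_idx]
  orphan <- which(is.na(tss_pos))
  if (length(orphan)) {
    osc <- slot_coords(p + seq_along(orphan) - 1L)
    tss_pos[orphan] <- osc$base + 2500L
    tss_chrom[orphan] <- osc$chrom
  }
  tss <- data.frame(gene = gene_ids, chrom = tss_chrom, tss = tss_pos,
                    strand = anno$strand, stringsAsFactors = FALSE)

  is_enh <- anno$cls %in% c("enhancer", "promoter_and_enhancer")
  enh_idx <- which(is_enh)
  # dual OCRs link their own gene; pure enhancers link a random gene
  enh_gene <- ifelse(is.na(ocr_gene[enh_idx]), anno$enh_gene_pick[enh_idx],
                     ocr_gene[enh_idx])
  ocr_gene[enh_idx] <- enh_gene
  enhancer_links <- data.frame(
    chrom = ocrs$chrom[enh_idx],
    start = ocrs$start[enh_idx] + anno$off[enh_idx],
    end = pmax(ocrs$start[enh_idx] + anno$off[enh_idx] + 60L,
               ocrs$end[enh_idx] - anno$off[enh_idx]),
    gene = gene_ids[enh_gene],
    tissue = "blood",
    ocr_id = ocrs$id[enh_idx],
    stringsAsFactors = FALSE
  )
  ocrs$linked_gene <- ifelse(is.na(ocr_gene), NA_character_,
                             gene_ids[ocr_gene])

  ## --- planted age effects with cross-modality coupling -----------------
  eff <- with_seed(substream_seed(config$seed, "effects"), {
    u <- stats::runif(p)
    tier <- rep("none", p)
    planted <- u < config$frac_opening + config$frac_closing
    tier[planted] <- sample(c("strong", "weak"), sum(planted),
                            replace = TRUE)
    sign <- ifelse(u < config$frac_opening, 1, -1)
    mag <- ifelse(tier == "strong", config$effect_strong,
                  ifelse(tier == "weak", config$effect_weak, 0))
    e <- ifelse(planted, sign * mag,
                stats::rnorm(p, 0, config$background_effect_sd))
    s_e <- stats::sd(e)
    degenerate_e <- !is.finite(s_e) || s_e < 1e-12
    # gene effects: couple to the gene's promoter OCR when it has one
    g <- config$expr_effect_sd * stats::rnorm(config$n_genes)
    z_p <- if (degenerate_e) rep(0, length(prom_idx)) else e[prom_idx] / s_e
    g[prom_gene] <- config$expr_effect_sd *
      (config$rho_promoter * z_p +
         sqrt(1 - config$rho_promoter^2) * stats::rnorm(length(prom_idx)))
    # pure-enhancer OCR effects: couple to their linked gene's effect
    pure_enh <- which(anno$cls == "enhancer")
    s_g <- stats::sd(g)
    z_g <- if (!is.finite(s_g) || s_g < 1e-12) rep(0, length(g)) else g / s_g
    enh_scale <- if (degenerate_e) 0 else s_e
    e[pure_enh] <- enh_scale *
      (config$rho_enhancer * z_g[ocr_gene[pure_enh]] +
         sqrt(1 - config$rho_enhancer^2) * stats::rnorm(length(pure_enh)))
    tier[pure_enh] <- "coupled"
    e_sex <- stats::rnorm(p, 0, config$sex_effect_sd)
    list(e = e, tier = tier, g = g, e_sex = e_sex)
  })

  ## --- CpG placement and methylation effects ----------------------------
  meth <- with_seed(substream_seed(config$seed, "meth_layout"), {
    n_in <- round(config$frac_cpg_in_ocr * config$n_cpgs)
    host <- c(sample.int(p, n_in, replace = TRUE),
              rep(NA_integer_, config$n_cpgs - n_in))
    pos <- integer(config$n_cpgs)
    pos[seq_len(n_in)] <- ocrs$start[host[seq_len(n_in)]] +
      floor(stats::runif(n_in) * ocrs$length_bp[host[seq_len(n_in)]])
    chrom <- character(config$n_cpgs)
    chrom[seq_len(n_in)] <- ocrs$chrom[host[seq_len(n_in)]]
    n_out <- config$n_cpgs - n_in
    if (n_out > 0) {
      gsl <- sample.int(p, n_out, replace = TRUE) - 1L
      gs <- slot_coords(gsl)
      pos[n_in + seq_len(n_out)] <- gs$base + 1500L +
        floor(stats::runif(n_out) * 3000)
      chrom[n_in + seq_len(n_out)] <- gs$chrom
    }
    rho <- rep(0, config$n_cpgs)
    hosted <- !is.na(host)
    hcls <- ifelse(hosted, ocrs$annotation[host], NA)
    rho[hosted & hcls == "enhancer"] <- config$rho_meth_acc_enhancer
    rho[hosted & hcls %in% c("promoter", "promoter_and_enhancer")] <-
      config$rho_meth_acc_promoter
    s_eff <- stats::sd(eff$e)
    if (!is.finite(s_eff) || s_eff < 1e-12) s_eff <- 1
    z_host <- ifelse(hosted, eff$e[host] / s_eff, 0)
    m <- config$meth_effect_sd *
      (rho * z_host + sqrt(1 - rho^2) * stats::rnorm(config$n_cpgs))
    list(host = host, pos = pos, chrom = chrom, m = m)
  })
  cpg_ids <- sprintf("cg%05d", seq_len(config$n_cpgs))
  cpg_table <- data.frame(cpg_id = cpg_ids, chrom = meth$chrom,
                          pos = meth$pos, stringsAsFactors = FALSE)

  ## --- accessibility counts ---------------------------------------------
  a <- (samples$age - mid_age) / age_sd
  counts <- with_seed(substream_seed(config$seed, "accessibility"), {
    b <- stats::rnorm(p, 0, 1)
    U <- matrix(stats::rnorm(p * nrow(cp), 0, config$celltype_profile_sd),
                nrow = p)
    profiles <- exp(b + U)                      # OCR x cell type
    base_mix <- profiles %*% t(f_true)          # OCR x sample
    shift <- outer(eff$e, a) +
      outer(eff$e_sex, as.numeric(samples$sex == "F")) +
      outer(eff$e, as.numeric(samples$condition == "case") *
              (config$condition_effect_years / age_sd))
    mu <- base_mix * exp(shift)
    rip <- exp(stats::rnorm(n, log(config$mean_reads_in_peaks),
                            config$libsize_log_sd))
    mu <- sweep(mu, 2, colSums(mu), "/") %*% diag(rip)
    matrix(stats::rnbinom(p * n, mu = mu, size = 1 / config$dispersion),
           nrow = p, dimnames = list(ocrs$id, sample_id))
  })
  norm <- normalize_accessibility(counts, ocrs$length_bp)

  ## --- expression --------------------------------------------------------
  expression <- with_seed(substream_seed(config$seed, "expression"), {
    base_g <- stats::rnorm(config$n_genes, 5, 2)
    base_g + outer(eff$g, a) +
      matrix(stats::rnorm(config$n_genes * n, 0, config$expr_noise_sd),
             nrow = config$n_genes)
  })
  dimnames(expression) <- list(gene_ids, sample_id)

  ## --- methylation -------------------------------------------------------
  methylation <- with_seed(substream_seed(config$seed, "methylation"), {
    mu0 <- stats::rnorm(config$n_cpgs, 0, 1.5)
    stats::plogis(mu0 + outer(meth$m, a) +
                    matrix(stats::rnorm(config$n_cpgs * n, 0,
                                        config$meth_noise_sd),
                           nrow = config$n_cpgs))
  })
  dimnames(methylation) <- list(cpg_ids, sample_id)

  truth <- list(
    ocr = data.frame(id = ocrs$id, annotation = ocrs$annotation,
                     tier = eff$tier, effect = eff$e,
                     sex_effect = eff$e_sex,
                     linked_gene = ocrs$linked_gene,
                     stringsAsFactors = FALSE),
    gene = data.frame(gene = gene_ids, effect = eff$g,
                      stringsAsFactors = FALSE),
    cpg = data.frame(cpg_id = cpg_ids, effect = meth$m,
                     host_ocr = ifelse(is.na(meth$host), NA_character_,
                                       ocrs$id[meth$host]),
                     stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_id, age = samples$age,
                         sex = samples$sex, condition = samples$condition,
                         f_true, stringsAsFactors = FALSE),
    age_sd_years = age_sd
  )

  list(ocrs = ocrs, tss = tss, enhancer_links = enhancer_links,
       counts = counts, normalized = norm$normalized,
       log_normalized = norm$log_normalized, expression = expression,
       methylation = methylation, cpg_table = cpg_table,
       samples = sample_table, truth = truth, config = config)
}

#' Fragment-level simulation configuration
#'
#' Small-scale settings for simulating per-sample fragment files and peak
#' calls that exercise consensus construction, cut-site counting and FRIP.
#'
#' @param n_samples,n_ocrs,n_genes,n_cpgs Cohort dimensions (kept small).
#' @param fragments_per_sample Fragments simulated per sample.
#' @param frip_target Probability that a fragment falls inside a true OCR.
#' @param dropout Per-sample probability that a true OCR is missing from
#'   that sample's peak calls.
#' @param jitter_bp Maximal boundary jitter of per-sample peak calls.
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution.
#' @param seed Base seed.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A config list of class `fragment_config`.
#' @export
fragment_config <- function(n_samples = 30, n_ocrs = 60, n_genes = 30,
                            n_cpgs = 40, fragments_per_sample = 3000,
                            frip_target = 0.5, dropout = 0.15,
                            jitter_bp = 25, fragment_len_mean = 80,
                            fragment_len_sd = 10, seed = 1, ...) {
  cfg <- list(
    cohort = cohort_config(n_samples = n_samples, n_ocrs = n_ocrs,
                           n_genes = n_genes, n_cpgs = n_cpgs,
                           mean_reads_in_peaks = 2 * fragments_per_sample,
                           seed = substream_seed(seed, "cohort"), ...),
    fragments_per_sample = fragments_per_sample,
    frip_target = frip_target, dropout = dropout, jitter_bp = jitter_bp,
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd, seed = seed
  )
  stopifnot(cfg$frip_target > 0, cfg$frip_target <= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- c("fragment_config", "list")
  cfg
}

#' Simulate per-sample fragment files and peak calls
#'
#' Fragments land inside a true OCR with probability `frip_target` (the OCR
#' chosen proportionally to the sample's simulated counts, so age structure
#' carries through) and otherwise in guaranteed OCR-free background between
#' slots. Per-sample peak calls are the true OCRs with the configured
#' dropout and boundary jitter, so consensus construction can be tested
#' against the known truth.
#'
#' @param config A [fragment_config()].
#' @return List with `fragments` (named list of BED data frames),
#'   `peak_calls` (named list), `ocrs` (true OCR set), `samples`, `cohort`
#'   (the underlying small cohort), `config`.
#' @export
generate_fragments <- function(config = fragment_config()) {
  stopifnot(inherits(config, "fragment_config"))
  cohort <- generate_cohort(config$cohort)
  ocrs <- cohort$ocrs
  p <- nrow(ocrs)
  n <- config$cohort$n_samples
  out <- with_seed(substream_seed(config$seed, "fragments"), {
    fragments <- vector("list", n)
    peak_calls <- vector("list", n)
    for (j in seq_len(n)) {
      nf <- config$fragments_per_sample
      n_in <- stats::rbinom(1, nf, config$frip_target)
      pick <- sample.int(p, n_in, replace = TRUE,
                         prob = cohort$counts[, j] + 1)
      len <- pmax(20L, round(stats::rnorm(n_in, config$fragment_len_mean,
                                          config$fragment_len_sd)))
      len <- pmin(len, ocrs$length_bp[pick] - 2L)
      fs <- ocrs$start[pick] +
        floor(stats::runif(n_in) * (ocrs$length_bp[pick] - len + 1))
      n_bg <- nf - n_in
      gsl <- sample.int(p, n_bg, replace = TRUE) - 1L
      gs <- slot_coords(gsl)
      blen <- pmax(20L, round(stats::rnorm(n_bg, config$fragment_len_mean,
                                           config$fragment_len_sd)))
      blen <- pmin(blen, 500L)
      bs <- gs$base + 1200L + floor(stats::runif(n_bg) * (3000 - blen))
      fragments[[j]] <- data.frame(
        chrom = c(ocrs$chrom[pick], gs$chrom),
        start = c(fs, bs), end = c(fs + len, bs + blen),
        stringsAsFactors = FALSE
      )
      keep <- stats::runif(p) >= config$dropout
      js <- round(stats::runif(p, -config$jitter_bp, config$jitter_bp))
      je <- round(stats::runif(p, -config$jitter_bp, config$jitter_bp))
      pk <- data.frame(
        chrom = ocrs$chrom, start = pmax(0, ocrs$start + js),
        end = ocrs$end + je, stringsAsFactors = FALSE
      )
      pk$end <- pmax(pk$end, pk$start + 50L)
      peak_calls[[j]] <- pk[keep, , drop = FALSE]
    }
    list(fragments = fragments, peak_calls = peak_calls)
  })
  names(out$fragments) <- cohort$samples$sample_id
  names(out$peak_calls) <- cohort$samples$sample_id
  list(fragments = out$fragments, peak_calls = out$peak_calls,
       ocrs = ocrs, samples = cohort$samples, cohort = cohort,
       config = config)
}
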