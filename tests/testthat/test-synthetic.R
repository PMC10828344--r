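test_that("generator is deterministic and invalid configs are rejected", {
  cfg <- cohort_config(n_samples = 25, n_ocrs = 150, n_genes = 60,
                       n_cpgs = 50, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$samples, b$samples)

  expect_error(cohort_config(frac_opening = 0.7, frac_closing = 0.6),
               "<= 1")
  expect_error(cohort_config(rho_promoter = 1.4), "coupling")
  expect_error(cohort_config(cell_populations = data.frame(
    population = c("monocytes", "granulocytes", "B", "NK", "CD4T", "CD8T"),
    baseline = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.2),
    slope_per_year = 0
  )), "sum to 1")
})

test_that("cohort structure is internally consistent", {
  co <- generate_cohort(cohort_config(n_samples = 30, n_ocrs = 200,
                                      n_genes = 80, n_cpgs = 60, seed = 2))
  expect_equal(dim(co$counts), c(200L, 30L))
  expect_equal(rownames(co$counts), co$ocrs$id)
  expect_equal(colnames(co$counts), co$samples$sample_id)
  expect_true(all(co$counts >= 0))
  expect_true(all(co$methylation > 0 & co$methylation < 1))
  expect_true(all(co$samples$age >= 20 & co$samples$age <= 74))
  # derived populations respect the hierarchy
  expect_equal(co$samples$T, co$samples$CD4T + co$samples$CD8T)
  expect_equal(co$samples$lymphocytes,
               co$samples$T + co$samples$B + co$samples$NK)
  # annotation recovered from the emitted TSS/enhancer resources matches truth
  ann <- annotate_ocrs(co$ocrs[, c("chrom", "start", "end", "id",
                                   "length_bp")],
                       co$tss, co$enhancer_links)
  expect_equal(ann$annotation, co$truth$ocr$annotation)
  # promoter-linked genes match the planted 1:1 assignment
  prom <- co$truth$ocr$annotation %in% c("promoter", "promoter_and_enhancer")
  expect_equal(ann$linked_gene[prom], co$truth$ocr$linked_gene[prom])
})

test_that("a null cohort produces approximately uniform q-values", {
  cfg <- cohort_config(n_samples = 60, n_ocrs = 800, n_genes = 300,
                       n_cpgs = 50, frac_opening = 0, frac_closing = 0,
                       background_effect_sd = 0, sex_effect_sd = 0,
                       cell_populations = data.frame(
                         population = c("monocytes", "granulocytes", "B",
                                        "NK", "CD4T", "CD8T"),
                         baseline = c(0.18, 0.03, 0.10, 0.12, 0.38, 0.19),
                         slope_per_year = 0
                       ),
                       seed = 12)
  co <- generate_cohort(cfg)
  tab <- age_correlations(co$log_normalized, co$samples$age)
  called <- sum(tab$class != "stable")
  expect_lte(called, 0.02 * nrow(tab))
  # p-values roughly uniform (jitter breaks discreteness ties)
  set.seed(1)
  pj <- pmin(pmax(tab$p_value + runif(nrow(tab), 0, 1e-8), 0), 1)
  expect_gt(suppressWarnings(ks.test(pj, "punif")$p.value), 1e-4)
})

test_that("NK fraction drifts with age at the calibrated strength", {
  co <- generate_cohort(cohort_config(seed = 3))
  r_nk <- cor(co$samples$NK, co$samples$age)
  expect_gt(r_nk, 0.15)
  expect_lt(r_nk, 0.45)
  # T cells decline
  expect_lt(cor(co$samples$T, co$samples$age), 0)
})

test_that("planted strong effects are recovered with the right sign", {
  co <- generate_cohort(cohort_config(seed = 7))
  tab <- age_correlations(co$log_normalized, co$samples$age)
  tr <- co$truth$ocr
  est <- tab$spearman_r[match(tr$id, tab$feature_id)]
  strong <- tr$tier == "strong"
  expect_gt(sum(strong), 20)
  expect_gte(mean(sign(est[strong]) == sign(tr$effect[strong])), 0.95)
})

test_that("fragment simulation hits the FRIP target and supports consensus recovery", {
  cfg <- fragment_config(n_samples = 12, n_ocrs = 40, n_genes = 20,
                         n_cpgs = 20, fragments_per_sample = 2500,
                         frip_target = 0.8, dropout = 0, jitter_bp = 0,
                         seed = 4)
  sim <- generate_fragments(cfg)
  # dropout 0, jitter 0: consensus equals the true OCR set
  cons <- build_consensus(sim$peak_calls, min_samples = 12)
  expect_equal(cons[, c("chrom", "start", "end")],
               sort_ocrs <- sim$ocrs[order(sim$ocrs$chrom, sim$ocrs$start),
                                     c("chrom", "start", "end")],
               ignore_attr = TRUE)
  frips <- vapply(sim$fragments, compute_frip, numeric(1), ocrs = sim$ocrs)
  expect_true(all(abs(frips - 0.8) < 0.03))
})

test_that("heavy peak-call dropout removes true OCRs from the consensus", {
  cfg <- fragment_config(n_samples = 12, n_ocrs = 40, n_genes = 20,
                         n_cpgs = 20, fragments_per_sample = 500,
                         dropout = 0.6, jitter_bp = 5, seed = 9)
  sim <- generate_fragments(cfg)
  cons <- build_consensus(sim$peak_calls, min_samples = 9)
  expect_lt(nrow(cons), nrow(sim$ocrs))
})

test_that("the fragment pipeline is byte-identical under a fixed config and seed", {
  cfg <- fragment_config(n_samples = 14, n_ocrs = 30, n_genes = 15,
                         n_cpgs = 15, fragments_per_sample = 800, seed = 21)
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  r1 <- run_pipeline(d1, cfg, min_samples = 7, depth_min = 100,
                     frip_min = 0.1, k = 4)
  r2 <- run_pipeline(d2, cfg, min_samples = 7, depth_min = 100,
                     frip_min = 0.1, k = 4)
  for (f in basename(r1$files)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("a condition planted along the aging axis shifts clock predictions as expected", {
  cfg <- cohort_config(n_samples = 420, condition_frac = 0.27,
                       condition_effect_years = 5, seed = 23)
  co <- generate_cohort(cfg)
  ctl <- which(co$samples$condition == "control")
  case <- which(co$samples$condition == "case")
  set.seed(1)
  train <- sample(ctl, 200)
  test <- c(head(setdiff(ctl, train), 100), head(case, 100))
  X <- t(co$log_normalized)
  y <- co$samples$age
  model <- train_final_clock(X[train, ], y[train],
                             assign_age_groups(y[train], 11, seed = 3))
  pred <- predict(model, X[test, ])
  cond <- ifelse(co$samples$condition[test] == "case", "positive",
                 "negative")
  dt <- make_delta_table(co$samples$sample_id[test], pred, y[test], cond)
  eff <- age_adjusted_effect(dt)
  expect_gt(eff$effect_years, 0)
  expect_lt(eff$p_value, 1e-6)
  # regularization attenuates the clock's response by its calibration
  # slope; the recovered effect should cover the slope-adjusted target
  ctl_test <- cond == "negative"
  slope <- coef(lm(pred[ctl_test] ~ y[test][ctl_test]))[2]
  target <- 5 * unname(slope)
  expect_true(eff$ci[1] < target && target < eff$ci[2])
  # raw group difference agrees in direction
  expect_lt(group_ttest(dt)$p_value, 1e-4)
})
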