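make_comps <- function(n, seed = 1) {
  set.seed(seed)
  comps <- matrix(abs(rnorm(n * 3, 0.2, 0.05)), n, 3,
                  dimnames = list(NULL, c("NK", "B", "CD8T")))
  comps
}

test_that("composition models recover exact linear dependence", {
  n <- 40
  comps <- make_comps(n)
  ages <- runif(n, 20, 74)
  mat <- rbind(nk2 = 2 * comps[, "NK"],
               noise = rnorm(n))
  fit <- fit_composition_models(mat, ages, comps)
  expect_equal(unname(fit$coefficients["nk2", "NK"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["nk2", "B"]), 0, tolerance = 1e-8)
  # correcting the same data flattens the dependent feature
  corr <- apply_composition_correction(fit, mat, comps)
  expect_lt(sd(corr["nk2", ]), 1e-10)
})

test_that("composition OLS matches the normal-equation oracle on a small design", {
  set.seed(42)
  n <- 12
  comps <- make_comps(n, 2)[, 1:2]
  ages <- runif(n, 20, 74)
  mat <- rbind(f1 = rnorm(n), f2 = rnorm(n))
  fit <- fit_composition_models(mat, ages, comps)
  X <- cbind(1, ages, comps)
  for (f in rownames(mat)) {
    expect_equal(unname(fit$coefficients[f, ]),
                 as.vector(oracle_ols(X, mat[f, ])), tolerance = 1e-10)
  }
})

test_that("rank-deficient composition designs error naming the collinear column", {
  n <- 20
  comps <- make_comps(n)
  comps <- cbind(comps, lymph = comps[, "NK"] + comps[, "B"] +
                   comps[, "CD8T"])
  # lymph = NK + B + CD8T exactly -> collinear
  comps2 <- cbind(comps[, 1:3], dupNK = comps[, "NK"])
  expect_error(
    fit_composition_models(rbind(f = rnorm(n)), runif(n, 20, 74), comps2),
    "dupNK"
  )
})

test_that("correction uses stored coefficients and training means only", {
  n <- 30
  comps <- make_comps(n, 3)
  ages <- runif(n, 20, 74)
  mat <- rbind(f = 1.5 * comps[, "NK"] + 0.2 * ages + rnorm(n, 0, 0.01))
  fit <- fit_composition_models(mat, ages, comps)
  # samples at the training-mean composition are unchanged
  at_mean <- matrix(rep(fit$comp_means, each = 4), 4,
                    dimnames = list(NULL, colnames(comps)))
  newmat <- rbind(f = rnorm(4))
  expect_equal(apply_composition_correction(fit, newmat, at_mean), newmat)
  # age trend survives correction (the age term is never subtracted)
  corrected <- apply_composition_correction(fit, mat, comps)
  b_age <- coef(lm(corrected["f", ] ~ ages))[2]
  expect_equal(unname(b_age), 0.2, tolerance = 0.01)
  expect_error(
    apply_composition_correction(fit, mat, comps[, c(2, 1, 3)]),
    "do not match"
  )
})

test_that("correction is idempotent: refit betas on corrected data are ~0", {
  set.seed(44)
  n <- 50
  comps <- make_comps(n, 4)
  ages <- runif(n, 20, 74)
  mat <- rbind(f1 = 2 * comps[, "NK"] - comps[, "B"] + rnorm(n, 0, 0.05),
               f2 = rnorm(n))
  fit <- fit_composition_models(mat, ages, comps)
  corr <- apply_composition_correction(fit, mat, comps)
  refit <- fit_composition_models(corr, ages, comps)
  expect_lt(max(abs(refit$coefficients[, colnames(comps)])), 1e-8)
  corr2 <- apply_composition_correction(refit, corr, comps)
  expect_equal(corr2, corr, tolerance = 1e-8)
})

test_that("sex offsets are removed while the age trend is preserved", {
  set.seed(45)
  n <- 80
  ages <- runif(n, 20, 74)
  sex <- rbinom(n, 1, 0.4)
  mat <- rbind(f = 0.3 * ages + 4 * sex + rnorm(n, 0, 0.3))
  corrected <- remove_covariate_preserving_age(mat, cbind(sex = sex), ages,
                                               preserve_age = TRUE)
  fit <- lm(corrected["f", ] ~ ages + sex)
  expect_equal(unname(coef(fit)["sex"]), 0, tolerance = 0.05)
  expect_equal(unname(coef(fit)["ages"]), 0.3, tolerance = 0.02)
  # matches the batch-removal reference implementation up to the per-feature
  # constant (the reference does not center the covariate before subtracting)
  skip_if_not_installed("limma")
  ref <- limma::removeBatchEffect(mat, covariates = cbind(sex = sex),
                                  design = cbind(1, ages))
  expect_equal(corrected - rowMeans(corrected), ref - rowMeans(ref),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("without age preservation, composition-mediated age signal is removed", {
  set.seed(46)
  n <- 100
  ages <- runif(n, 20, 74)
  nk <- 0.1 + 0.002 * ages + rnorm(n, 0, 0.005)
  mat <- rbind(f = 5 * nk + rnorm(n, 0, 0.02))  # age signal fully via NK
  keep_age <- remove_covariate_preserving_age(mat, cbind(NK = nk), ages,
                                              preserve_age = TRUE)
  drop_age <- remove_covariate_preserving_age(mat, cbind(NK = nk), ages,
                                              preserve_age = FALSE)
  r_drop <- cor(drop_age["f", ], ages)
  expect_lt(abs(r_drop), 0.15)
  # orthogonal covariate leaves the feature untouched
  orth <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "z"))
  mat2 <- rbind(f = 0.1 * ages + rnorm(n, 0, 0.1))
  corr2 <- remove_covariate_preserving_age(mat2, orth, ages, TRUE)
  expect_equal(corr2["f", ], mat2["f", ], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("full-data correction with age preserved keeps per-feature age slopes", {
  set.seed(47)
  n <- 60
  ages <- runif(n, 20, 74)
  covs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  mat <- rbind(f1 = 0.2 * ages + rnorm(n, 0, 0.2),
               f2 = -0.1 * ages + rnorm(n, 0, 0.2))
  corrected <- remove_covariate_preserving_age(mat, covs, ages, TRUE)
  for (f in rownames(mat)) {
    s0 <- coef(lm(mat[f, ] ~ ages))[2]
    s1 <- coef(lm(corrected[f, ] ~ ages))[2]
    expect_equal(unname(s1), unname(s0), tolerance = 0.02)
  }
})

test_that("composition_explained_matrix keeps only intercept + composition fit", {
  set.seed(48)
  n <- 50
  comps <- make_comps(n, 5)
  ages <- runif(n, 20, 74)
  mat <- rbind(f = 3 * comps[, "B"] + 0.2 * ages + rnorm(n, 0, 0.05))
  kept <- composition_explained_matrix(mat, ages, comps)
  fit <- fit_composition_models(mat, ages, comps)
  manual <- fit$coefficients["f", "(Intercept)"] +
    as.vector(comps %*% fit$coefficients["f", colnames(comps)])
  expect_equal(unname(kept["f", ]), manual, tolerance = 1e-10)
  # the age component is gone up to the age-composition correlation
  expect_lt(abs(coef(lm(kept["f", ] ~ ages))[2]), 0.05)
})

test_that("within-CV correction never uses test-set information", {
  set.seed(49)
  n <- 60
  p <- 40
  ages <- runif(n, 20, 74)
  comps <- make_comps(n, 6)
  mat <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("o", 1:p), paste0("s", 1:n)))
  mat[1, ] <- mat[1, ] + 0.1 * ages
  folds <- rep(1:5, length.out = n)
  cv <- cv_corrected_clock(mat, ages, comps, folds,
                           lambda_grid = c(0.05, 0.5), alpha_grid = 0.5)
  # perturb test-fold ages: predictions for that fold must be unchanged
  ages2 <- ages
  ages2[folds == 2] <- ages2[folds == 2] + 30
  cv2 <- cv_corrected_clock(mat, ages2, comps, folds,
                            lambda_grid = c(0.05, 0.5), alpha_grid = 0.5)
  expect_equal(cv$predictions$predicted[folds == 2],
               cv2$predictions$predicted[folds == 2], tolerance = 1e-8)
})

test_that("zero planted composition effect leaves the corrected clock unchanged", {
  set.seed(50)
  n <- 55
  p <- 60
  ages <- runif(n, 20, 74)
  comps <- make_comps(n, 7)
  mat <- matrix(rnorm(p * n, 5, 0.3), p, n,
                dimnames = list(paste0("o", 1:p), paste0("s", 1:n)))
  for (i in 1:10) mat[i, ] <- mat[i, ] + 0.05 * (ages - mean(ages))
  folds <- assign_age_groups(ages, 5, seed = 1)
  cv_plain <- nested_cv(t(mat), ages, folds, lambda_grid = c(0.05, 0.5),
                        alpha_grid = 0.5)
  cv_corr <- cv_corrected_clock(mat, ages, comps, folds,
                                lambda_grid = c(0.05, 0.5), alpha_grid = 0.5)
  expect_equal(cv_corr$aggregate$rmse_mean, cv_plain$aggregate$rmse_mean,
               tolerance = 0.15)
})
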