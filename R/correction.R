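# Shared OLS helper: coefficients for every feature (rows of `mat`) on a
# common design matrix, via a single QR decomposition. Errors on
# rank-deficient designs, naming the collinear columns.
fit_feature_ols <- function(mat, design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- t(qr.coef(qrd, t(mat)))
  colnames(B) <- colnames(design)
  B
}

#' Fit per-feature accessibility models on age and cell composition
#'
#' Ordinary least squares of each feature on an intercept, age and the cell
#' population fractions. The stored composition coefficients and training
#' composition means are later used to subtract the composition effect from
#' train and test data without re-estimation.
#'
#' @param mat Feature x sample matrix.
#' @param ages Sample ages.
#' @param compositions Samples x populations matrix/data frame of cell
#'   fractions (columns named by population).
#' @return A `composition_fit`: coefficient matrix (feature x
#'   `(intercept, age, populations...)`), population labels, training
#'   composition means.
#' @export
fit_composition_models <- function(mat, ages, compositions) {
  comps <- as.matrix(compositions)
  stopifnot(ncol(mat) == length(ages), nrow(comps) == length(ages),
            all(is.finite(comps)))
  if (length(ages) < ncol(comps) + 2) {
    stop("need at least p + 2 samples for p composition covariates")
  }
  design <- cbind(`(Intercept)` = 1, age = ages, comps)
  B <- fit_feature_ols(mat, design)
  structure(list(
    coefficients = B,
    populations = colnames(comps),
    comp_means = colMeans(comps)
  ), class = "composition_fit")
}

#' Subtract the cell-composition effect using stored coefficients
#'
#' For each feature, `beta_c * (composition_c - training mean_c)` is summed
#' over populations and subtracted. The age term of the fit is not
#' subtracted, so the age effect is preserved; applying to test samples uses
#' the training coefficients without refitting.
#'
#' @param fit A `composition_fit`.
#' @param mat Feature x sample matrix to correct.
#' @param compositions Samples x populations fractions for these samples.
#' @return Corrected matrix of the same shape.
#' @export
apply_composition_correction <- function(fit, mat, compositions) {
  comps <- as.matrix(compositions)
  if (!identical(colnames(comps), fit$populations)) {
    stop("composition columns do not match the fitted populations")
  }
  cc <- sweep(comps, 2, fit$comp_means)
  mat - fit$coefficients[, fit$populations, drop = FALSE] %*% t(cc)
}

#' Remove covariate effects, optionally preserving the age trend
#'
#' Per feature, accessibility is regressed on an intercept, optionally age,
#' and the covariates; only the (mean-centered) covariate component is then
#' subtracted. With `preserve_age = TRUE` the age term in the design protects
#' variance explained by age from removal (the counterpart of including age
#' in the design of batch-removal tools); with `preserve_age = FALSE` shared
#' age/covariate variance is removed together with the covariates.
#'
#' @param mat Feature x sample matrix.
#' @param covariate_design Samples x covariates matrix/data frame (e.g. a
#'   binary sex indicator, cell fractions).
#' @param ages Sample ages (used when `preserve_age = TRUE`).
#' @param preserve_age Keep the age effect out of the removed component.
#' @return Corrected matrix.
#' @export
remove_covariate_preserving_age <- function(mat, covariate_design, ages,
                                            preserve_age = TRUE) {
  cov <- as.matrix(covariate_design)
  stopifnot(ncol(mat) == nrow(cov))
  design <- if (preserve_age) {
    cbind(`(Intercept)` = 1, age = ages, cov)
  } else {
    cbind(`(Intercept)` = 1, cov)
  }
  B <- fit_feature_ols(mat, design)
  ccov <- scale(cov, center = TRUE, scale = FALSE)
  mat - B[, colnames(cov), drop = FALSE] %*% t(ccov)
}

#' Keep only the composition-explained component
#'
#' The inverse experiment to composition correction: each feature is replaced
#' by the part of its age/composition fit attributable to the intercept and
#' cell composition, discarding both the age component and the residual
#' (cell-intrinsic) variation. Clocks trained on this matrix can only exploit
#' composition-mediated signal.
#'
#' @inheritParams fit_composition_models
#' @return Matrix of the same shape holding intercept + composition fit.
#' @export
composition_explained_matrix <- function(mat, ages, compositions) {
  fit <- fit_composition_models(mat, ages, compositions)
  comps <- as.matrix(compositions)
  fit$coefficients[, "(Intercept)"] +
    fit$coefficients[, fit$populations, drop = FALSE] %*% t(comps)
}

#' Nested CV with train-estimated cell-composition correction
#'
#' Inside every outer fold, composition models are fitted on the training
#' samples only (accessibility ~ age + composition) and their composition
#' coefficients correct both the training and the held-out test samples;
#' hyperparameter tuning and fitting then proceed as in [nested_cv()]. Test
#' ages never enter the correction.
#'
#' @param mat Feature x sample matrix.
#' @param ages Sample ages.
#' @param compositions Samples x populations cell fractions.
#' @param folds Outer group assignment.
#' @param lambda_grid,alpha_grid Hyperparameter grids.
#' @return A `cv_report`.
#' @export
cv_corrected_clock <- function(mat, ages, compositions, folds,
                               lambda_grid = default_grids()$lambda,
                               alpha_grid = default_grids()$alpha) {
  comps <- as.matrix(compositions)
  X <- t(mat)
  transform <- function(Xtr, ytr, Xte, te_idx) {
    tr_idx <- setdiff(seq_len(nrow(comps)), te_idx)
    fit <- fit_composition_models(t(Xtr), ytr,
                                  comps[tr_idx, , drop = FALSE])
    list(
      Xtr = t(apply_composition_correction(fit, t(Xtr),
                                           comps[tr_idx, , drop = FALSE])),
      Xte = t(apply_composition_correction(fit, t(Xte),
                                           comps[te_idx, , drop = FALSE]))
    )
  }
  nested_cv(X, ages, folds, lambda_grid, alpha_grid,
            fold_transform = transform)
}
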