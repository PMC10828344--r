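# Standardizer: per-feature mean and population standard deviation (the
# convention of the scaler used for clock training); features with ~zero
# training variance are dropped from the model (coefficient fixed at 0).
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  list(mean = mu, sd = sd, keep = sd > 1e-12)
}

std_apply <- function(X, std) {
  sweep(sweep(X[, std$keep, drop = FALSE], 2, std$mean[std$keep]), 2,
        std$sd[std$keep], "/")
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# glmnet internally standardizes the response, which leaves the L1 part of
# the penalty on the documented scale but divides the ridge part by the
# population sd of y. Calling glmnet with lambda scaled by
# c = alpha + (1 - alpha) * sd(y) and alpha / c makes it minimize the
# intended objective (1/2n)RSS + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# across the whole path.
glmnet_scale <- function(y, alpha) {
  sdy <- sqrt(mean((y - mean(y))^2))
  if (sdy < 1e-12) sdy <- 1
  max(alpha + (1 - alpha) * sdy, 1e-12)
}

# Exact elastic-net refinement on standardized (centered) features: active-set
# solve of the stationarity equations with sign-feasibility handling, warm
# started from the glmnet solution. Returns the exact minimizer, so the KKT
# conditions hold to solver precision.
refine_elastic_net <- function(Xs, y, beta, lambda, alpha, max_iter = 100) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  b0 <- mean(y)
  yc <- y - b0
  la <- lambda * alpha
  lr <- lambda * (1 - alpha)
  if (p == 0) return(list(beta = numeric(0), intercept = b0))
  if (la == 0) {
    # pure ridge (or unpenalized, solved as minimum-norm OLS) via SVD
    sv <- svd(Xs)
    d <- sv$d
    uy <- crossprod(sv$u, yc)
    w <- if (lr > 0) (d / n) / (d^2 / n + lr) else ifelse(d > 1e-10, 1 / d, 0)
    return(list(beta = as.vector(sv$v %*% (w * uy)), intercept = b0))
  }
  s <- sign(beta)
  A <- which(beta != 0)
  g_full <- function(bA, A) {
    r <- if (length(A)) yc - Xs[, A, drop = FALSE] %*% bA else yc
    as.vector(crossprod(Xs, r) / n)
  }
  bA <- beta[A]
  for (iter in seq_len(max_iter)) {
    repeat {
      if (!length(A)) {
        bA <- numeric(0)
        break
      }
      XA <- Xs[, A, drop = FALSE]
      M <- crossprod(XA) / n
      diag(M) <- diag(M) + lr
      rhs <- as.vector(crossprod(XA, yc)) / n - la * s[A]
      bA <- tryCatch(solve(M, rhs), error = function(e) {
        diag(M) <- diag(M) + 1e-8
        solve(M, rhs)
      })
      flip <- which(sign(bA) != s[A])
      if (!length(flip)) break
      A <- A[-flip]
    }
    g <- g_full(bA, A)
    inact <- setdiff(seq_len(p), A)
    viol <- inact[abs(g[inact]) > la + 1e-10]
    if (!length(viol)) {
      beta <- numeric(p)
      beta[A] <- bA
      return(list(beta = beta, intercept = b0))
    }
    # admit the single worst violator per iteration for stability
    worst <- viol[which.max(abs(g[viol]))]
    s[worst] <- sign(g[worst])
    A <- sort(c(A, worst))
  }
  # fallback: cyclic coordinate descent from the current iterate
  beta <- numeric(p)
  beta[A] <- bA
  r <- as.vector(yc - Xs %*% beta)
  for (pass in seq_len(2000)) {
    for (j in seq_len(p)) {
      bj <- beta[j]
      z <- mean(Xs[, j] * r) + bj
      bn <- soft_threshold(z, la) / (1 + lr)
      if (bn != bj) {
        r <- r + Xs[, j] * (bj - bn)
        beta[j] <- bn
      }
    }
    if (pass %% 10 == 0) {
      g <- as.vector(crossprod(Xs, r) / n)
      ok_in <- all(abs(g[beta == 0]) <= la + 1e-8)
      act <- which(beta != 0)
      ok_act <- !length(act) ||
        max(abs(g[act] - la * sign(beta[act]) - lr * beta[act])) <= 1e-8
      if (ok_in && ok_act) break
    }
  }
  list(beta = beta, intercept = b0)
}

#' Fit an elastic-net age model
#'
#' Minimizes `(1/2n) sum (y - yhat)^2 + lambda (alpha_l1 |b|_1 +
#' (1-alpha_l1)/2 |b|_2^2)` with an unpenalized intercept. Features are
#' standardized internally with training means and (population) standard
#' deviations, which are stored in the model; zero-variance features are
#' dropped with a message and keep coefficient zero. The solution comes from
#' a glmnet regularization path warm start followed by coordinate-descent
#' refinement, so the KKT conditions hold to high precision.
#'
#' @param X Samples x features numeric matrix (column names = feature ids).
#' @param y Ages in years.
#' @param lambda Overall penalty (>= 0).
#' @param alpha_l1 L1 mixing parameter in `[0, 1]`.
#' @return A `clock_model`: feature ids, standardizer, coefficients (on the
#'   standardized scale), intercept, hyperparameters.
#' @export
fit_elastic_net <- function(X, y, lambda, alpha_l1) {
  stopifnot(lambda >= 0, alpha_l1 >= 0, alpha_l1 <= 1,
            nrow(X) == length(y), !anyNA(X), !anyNA(y))
  std <- std_fit(X)
  if (any(!std$keep)) {
    message(sum(!std$keep), " zero-variance feature(s) dropped")
  }
  Xs <- std_apply(X, std)
  p <- ncol(Xs)
  n <- nrow(Xs)
  beta <- rep(0, p)
  if (lambda > 0 && alpha_l1 > 0 && p > 0) {
    sc <- glmnet_scale(y, alpha_l1)
    lmax <- max(abs(crossprod(Xs, y - mean(y)) / n)) / max(alpha_l1, 1e-3)
    lam_hi <- max(lmax, lambda * 1.001)
    path <- sort(unique(c(lambda, exp(seq(log(lam_hi), log(lambda),
                                          length.out = 30)))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(Xs, y, alpha = alpha_l1 / sc, lambda = sc * path,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-10, maxit = 1e6)
    beta <- as.vector(fit$beta[, which.min(abs(fit$lambda - sc * lambda))])
  }
  pol <- refine_elastic_net(Xs, y, beta, lambda, alpha_l1)
  coefficients <- stats::setNames(rep(0, length(std$keep)), colnames(X))
  coefficients[std$keep] <- pol$beta
  structure(list(
    feature_ids = colnames(X),
    standardizer = std,
    coefficients = coefficients,
    intercept = pol$intercept,
    hyperparams = list(lambda = lambda, alpha_l1 = alpha_l1)
  ), class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Elastic-net clock model:", length(x$feature_ids), "features,",
      sum(x$coefficients != 0), "selected; lambda =",
      signif(x$hyperparams$lambda, 3), "alpha_l1 =",
      x$hyperparams$alpha_l1, "\n")
  invisible(x)
}

#' Predict ages from a clock model
#'
#' New data are standardized with the stored training means and standard
#' deviations before applying the coefficients and intercept.
#'
#' @param object A `clock_model`.
#' @param newdata Samples x features matrix containing every model feature.
#' @param ... Ignored.
#' @return Numeric vector of predicted ages.
#' @export
predict.clock_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing)) {
    stop("newdata is missing model features: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) paste0(" (+", length(missing) - 5, " more)"))
  }
  X <- newdata[, object$feature_ids, drop = FALSE]
  Xs <- std_apply(X, object$standardizer)
  as.vector(object$intercept +
              Xs %*% object$coefficients[object$standardizer$keep])
}

#' Age-prediction metrics
#'
#' @param predicted,true Equal-length numeric vectors (n >= 2).
#' @return List with `rmse`, `mae_median` (median absolute error),
#'   `pearson_r` (`NA` with `r_defined = FALSE` when either vector is
#'   constant).
#' @export
clock_metrics <- function(predicted, true) {
  stopifnot(length(predicted) == length(true), length(true) >= 2)
  res <- predicted - true
  r_ok <- stats::sd(predicted) > 0 && stats::sd(true) > 0
  list(
    rmse = sqrt(mean(res^2)),
    mae_median = stats::median(abs(res)),
    pearson_r = if (r_ok) stats::cor(predicted, true) else NA_real_,
    r_defined = r_ok
  )
}

#' Age-balanced group assignment for cross-validation
#'
#' Samples are sorted by age and dealt into `k` groups in consecutive blocks
#' of `k` (the within-block order shuffled by `seed`), so every group
#' receives one sample from each age stratum and the age composition of each
#' group covers the cohort range approximately uniformly.
#'
#' @param ages Ages in years.
#' @param k Number of groups (default 11).
#' @param seed Integer seed for the within-block shuffles.
#' @return Integer vector of group ids in `1..k`, aligned with `ages`.
#' @export
assign_age_groups <- function(ages, k = 11, seed = 1) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  n <- length(ages)
  if (n < k) stop("need at least k samples")
  ord <- order(ages)
  groups <- integer(n)
  with_seed(seed, {
    i <- 1L
    while (i <= n) {
      block <- ord[i:min(i + k - 1L, n)]
      m <- length(block)
      gids <- if (m == k) sample.int(k) else sample.int(k, m)
      groups[block] <- gids
      i <- i + k
    }
  })
  groups
}

# Standardize on the training rows, fit a glmnet path over the lambda grid at
# one alpha, and return test-set predictions for every lambda (test columns
# = lambda grid order).
en_path_predict <- function(Xtr, ytr, Xte, lambda_grid, alpha) {
  std <- std_fit(Xtr)
  if (!any(std$keep)) {
    return(matrix(mean(ytr), nrow = nrow(Xte), ncol = length(lambda_grid)))
  }
  Xs <- std_apply(Xtr, std)
  sc <- glmnet_scale(ytr, alpha)
  path <- sort(unique(lambda_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, ytr, alpha = alpha / sc, lambda = sc * path,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-8, maxit = 1e6)
  pred <- stats::predict(fit, newx = std_apply(Xte, std),
                         s = sc * lambda_grid)
  matrix(pred, nrow = nrow(Xte))
}

#' Default hyperparameter grids
#'
#' 20 log-spaced lambda values over `[1e-3, 1e2]` (on the standardized
#' feature scale) and alpha in `{0.1, 0.5, 0.9}`.
#'
#' @return List with `lambda` and `alpha` vectors.
#' @export
default_grids <- function() {
  list(lambda = exp(seq(log(1e-3), log(1e2), length.out = 20)),
       alpha = c(0.1, 0.5, 0.9))
}

# Inner leave-one-group-out hyperparameter selection: mean RMSE over inner
# folds for every (alpha, lambda); deterministic tie-breaking (first
# strictly-better combination wins with alphas ascending and lambdas
# descending).
select_hyperparams <- function(X, y, groups, lambda_grid, alpha_grid) {
  lam_desc <- sort(unique(lambda_grid), decreasing = TRUE)
  alphas <- sort(unique(alpha_grid))
  sse <- matrix(0, nrow = length(alphas), ncol = length(lam_desc))
  nobs <- 0
  for (h in sort(unique(groups))) {
    tr <- groups != h
    if (all(tr) || !any(tr)) next
    for (a in seq_along(alphas)) {
      pred <- en_path_predict(X[tr, , drop = FALSE], y[tr],
                              X[!tr, , drop = FALSE], lam_desc, alphas[a])
      sse[a, ] <- sse[a, ] + colSums((pred - y[!tr])^2)
    }
    nobs <- nobs + sum(!tr)
  }
  rmse <- sqrt(sse / nobs)
  best <- which(rmse == min(rmse), arr.ind = TRUE)[1, ]
  list(alpha = alphas[best[1]], lambda = lam_desc[best[2]],
       rmse = min(rmse))
}

#' Nested leave-one-group-out cross-validation
#'
#' For every outer group, the inner loop runs leave-one-group-out CV over the
#' remaining groups to select `(lambda, alpha)` by mean inner RMSE; a model
#' with the selected hyperparameters is refit on all non-test samples and
#' predicts the held-out group, so each sample is predicted exactly once by a
#' model that never saw it. Per-fold RMSE, median absolute error and Pearson
#' r are aggregated as mean and standard deviation.
#'
#' @param X Samples x features matrix.
#' @param y Ages.
#' @param folds Integer group assignment from [assign_age_groups()].
#' @param lambda_grid,alpha_grid Hyperparameter grids (defaults from
#'   [default_grids()]).
#' @param fold_transform Optional function `(Xtr, ytr, Xte, te_idx)` returning
#'   `list(Xtr, Xte)`; applied inside each outer fold before tuning and
#'   fitting (used for train-estimated corrections).
#' @return A `cv_report`: per-sample out-of-fold `predictions`, `per_fold`
#'   metrics (with selected hyperparameters and feature counts), and
#'   `aggregate` mean/sd of each metric.
#' @export
nested_cv <- function(X, y, folds, lambda_grid = default_grids()$lambda,
                      alpha_grid = default_grids()$alpha,
                      fold_transform = NULL) {
  stopifnot(nrow(X) == length(y), length(folds) == length(y),
            length(lambda_grid) >= 1, length(alpha_grid) >= 1)
  gl <- sort(unique(folds))
  if (length(gl) < 2) stop("need at least 2 groups")
  pred_all <- rep(NA_real_, length(y))
  per_fold <- list()
  for (g in gl) {
    te <- folds == g
    tr <- !te
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (!is.null(fold_transform)) {
      tf <- fold_transform(Xtr, y[tr], Xte, which(te))
      Xtr <- tf$Xtr
      Xte <- tf$Xte
    }
    hp <- select_hyperparams(Xtr, y[tr], folds[tr], lambda_grid, alpha_grid)
    model <- fit_elastic_net(Xtr, y[tr], hp$lambda, hp$alpha)
    pred <- predict(model, Xte)
    pred_all[te] <- pred
    m <- clock_metrics(pred, y[te])
    per_fold[[length(per_fold) + 1]] <- data.frame(
      fold = g, n_test = sum(te), rmse = m$rmse, mae_median = m$mae_median,
      pearson_r = m$pearson_r, n_selected = sum(model$coefficients != 0),
      lambda = hp$lambda, alpha = hp$alpha
    )
  }
  per_fold <- do.call(rbind, per_fold)
  agg <- clock_metrics(pred_all, y)
  structure(list(
    predictions = data.frame(
      sample = if (!is.null(rownames(X))) rownames(X) else seq_along(y),
      age = y, predicted = pred_all, fold = folds
    ),
    per_fold = per_fold,
    aggregate = list(
      rmse_mean = mean(per_fold$rmse), rmse_sd = stats::sd(per_fold$rmse),
      mae_median_mean = mean(per_fold$mae_median),
      mae_median_sd = stats::sd(per_fold$mae_median),
      # folds with constant predictions have undefined r and are omitted
      pearson_r_mean = mean(per_fold$pearson_r, na.rm = TRUE),
      pearson_r_sd = stats::sd(per_fold$pearson_r, na.rm = TRUE),
      n_folds_r_defined = sum(!is.na(per_fold$pearson_r)),
      n_selected_mean = mean(per_fold$n_selected)
    ),
    pooled = agg
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "Nested CV over %d folds: RMSE %.2f +/- %.2f, median AE %.2f +/- %.2f, r %.3f +/- %.3f (mean %0.f features)\n",
    nrow(x$per_fold), a$rmse_mean, a$rmse_sd, a$mae_median_mean,
    a$mae_median_sd, a$pearson_r_mean, a$pearson_r_sd, a$n_selected_mean))
  invisible(x)
}

#' Train the final clock on all samples
#'
#' Hyperparameters are selected by (non-nested) leave-one-group-out CV over
#' all samples and the final elastic net is refit on the full data.
#'
#' @inheritParams nested_cv
#' @return A `clock_model` with a `selection` attribute recording the chosen
#'   hyperparameters and their CV RMSE.
#' @export
train_final_clock <- function(X, y, folds,
                              lambda_grid = default_grids()$lambda,
                              alpha_grid = default_grids()$alpha) {
  hp <- select_hyperparams(X, y, folds, lambda_grid, alpha_grid)
  model <- fit_elastic_net(X, y, hp$lambda, hp$alpha)
  attr(model, "selection") <- hp
  model
}

#' Concatenate accessibility and expression features
#'
#' Stacks two feature x sample matrices over their shared samples with
#' modality-tagged feature ids (`atac:`/`rna:` prefixes); downstream
#' standardization in clock training puts both blocks on the same scale.
#'
#' @param atac_matrix,rna_matrix Feature x sample matrices.
#' @param prefixes Length-2 character vector of id prefixes.
#' @return Combined feature x sample matrix over the shared samples.
#' @export
concat_multiomic <- function(atac_matrix, rna_matrix,
                             prefixes = c("atac", "rna")) {
  common <- intersect(colnames(atac_matrix), colnames(rna_matrix))
  if (!length(common)) stop("no shared samples between modalities")
  a <- atac_matrix[, common, drop = FALSE]
  r <- rna_matrix[, common, drop = FALSE]
  if (nrow(a)) rownames(a) <- paste0(prefixes[1], ":", rownames(a))
  if (nrow(r)) rownames(r) <- paste0(prefixes[2], ":", rownames(r))
  out <- rbind(a, r)
  if (anyDuplicated(rownames(out))) stop("feature id collision after prefixing")
  out
}

#' Serialize a clock model to JSON
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @export
save_clock_model <- function(model, path) {
  jsonlite::write_json(list(
    feature_ids = model$feature_ids,
    mean = unname(model$standardizer$mean),
    sd = unname(model$standardizer$sd),
    keep = unname(model$standardizer$keep),
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    hyperparams = model$hyperparams
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a clock model from JSON
#'
#' @param path Path written by [save_clock_model()].
#' @return A `clock_model`.
#' @export
load_clock_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    feature_ids = x$feature_ids,
    standardizer = list(
      mean = stats::setNames(x$mean, x$feature_ids),
      sd = stats::setNames(x$sd, x$feature_ids),
      keep = stats::setNames(x$keep, x$feature_ids)
    ),
    coefficients = stats::setNames(x$coefficients, x$feature_ids),
    intercept = x$intercept,
    hyperparams = x$hyperparams
  ), class = "clock_model")
}
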