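test_that("age-balanced group assignment deals sorted blocks round-robin", {
  ages <- 20:41          # 22 samples, k = 11 -> 2 per group
  g <- assign_age_groups(ages, k = 11, seed = 1)
  expect_equal(sort(unique(g)), 1:11)
  expect_true(all(table(g) == 2))
  # one member from each age block
  for (k in 1:11) {
    got <- sort(ages[g == k])
    expect_true(got[1] <= 30 && got[2] >= 31)
  }
  # n = k -> singleton groups; determinism under the same seed
  g1 <- assign_age_groups(runif(11, 20, 74), k = 11, seed = 5)
  expect_true(all(table(g1) == 1))
  expect_identical(assign_age_groups(ages, 11, 9),
                   assign_age_groups(ages, 11, 9))
  expect_error(assign_age_groups(ages, k = 1, seed = 1), ">= 2")
})

test_that("each CV group spans most of the cohort age range", {
  set.seed(2)
  ages <- runif(150, 20, 74)
  g <- assign_age_groups(ages, k = 11, seed = 3)
  cohort_range <- diff(range(ages))
  for (k in 1:11) {
    expect_gte(diff(range(ages[g == k])), 0.6 * cohort_range)
  }
})

test_that("huge penalties give the intercept-only model", {
  set.seed(10)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(20, 50, 10)
  m <- fit_elastic_net(X, y, lambda = 1e6, alpha_l1 = 0.5)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, mean(y), tolerance = 1e-10)
  expect_equal(unname(predict(m, X)), rep(mean(y), 20), tolerance = 1e-10)
})

test_that("alpha 0 matches the ridge closed form on a small instance", {
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- c(30, 45, 50, 62, 28)
  lambda <- 0.7
  m <- fit_elastic_net(X, y, lambda, alpha_l1 = 0)
  std <- m$standardizer
  Xs <- scale(X, center = std$mean, scale = std$sd)
  n <- 5
  b_oracle <- solve(t(Xs) %*% Xs + n * lambda * diag(3),
                    t(Xs) %*% (y - mean(y)))
  expect_equal(unname(m$coefficients), as.vector(b_oracle),
               tolerance = 1e-8)
})

test_that("KKT conditions hold at the elastic-net solution", {
  set.seed(12)
  n <- 60
  p <- 120
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- X[, 1] * 3 - X[, 2] * 2 + rnorm(n, 0, 0.5) + 50
  for (cfg in list(c(0.05, 0.5), c(0.2, 0.9), c(0.5, 0.1))) {
    lambda <- cfg[1]
    alpha <- cfg[2]
    m <- fit_elastic_net(X, y, lambda, alpha)
    Xs <- scale(X, center = m$standardizer$mean,
                scale = m$standardizer$sd)
    b <- m$coefficients
    r <- y - m$intercept - Xs %*% b
    g <- as.vector(crossprod(Xs, r) / n)
    zero <- b == 0
    expect_lte(max(abs(g[zero])), lambda * alpha + 1e-6)
    act <- which(!zero)
    expect_lte(max(abs(g[act] - lambda * alpha * sign(b[act]) -
                         lambda * (1 - alpha) * b[act])), 1e-6)
  }
})

test_that("planted sparse signals get the largest coefficients", {
  set.seed(13)
  n <- 80
  p <- 100
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 40 + 4 * X[, 5] - 3 * X[, 50] + 2 * X[, 95] + rnorm(n, 0, 0.3)
  m <- fit_elastic_net(X, y, lambda = 0.05, alpha_l1 = 0.9)
  top <- order(-abs(m$coefficients))[1:3]
  expect_setequal(colnames(X)[top], c("f5", "f50", "f95"))
})

test_that("zero-variance features are dropped with zero coefficients", {
  set.seed(14)
  X <- cbind(flat = rep(3, 30),
             matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("f", 1:3))))
  y <- rnorm(30, 50, 5)
  expect_message(m <- fit_elastic_net(X, y, 0.1, 0.5), "zero-variance")
  expect_equal(unname(m$coefficients["flat"]), 0)
  expect_equal(length(predict(m, X)), 30)
})

test_that("prediction standardizes with stored training parameters", {
  set.seed(15)
  X <- matrix(rnorm(200, 10, 4), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(20, 50, 8)
  m <- fit_elastic_net(X, y, 0.1, 0.5)
  # a sample at the training feature means predicts the intercept
  at_mean <- matrix(m$standardizer$mean, 1,
                    dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(m, at_mean)), m$intercept, tolerance = 1e-10)
  # duplicated samples get identical predictions
  p2 <- predict(m, X[c(3, 3), , drop = FALSE])
  expect_equal(p2[1], p2[2])
  expect_error(predict(m, X[, 1:5]), "missing model features")
})

test_that("metrics follow their definitions including the median AE", {
  m <- clock_metrics(c(25, 35), c(20, 40))
  expect_equal(m$rmse, 5)
  expect_equal(m$mae_median, 5)
  expect_equal(m$pearson_r, 1)
  m2 <- clock_metrics(c(22, 32, 47) + 2, c(22, 32, 47))
  expect_equal(m2$rmse, 2)
  expect_equal(m2$mae_median, 2)
  expect_equal(m2$pearson_r, 1)
  m3 <- clock_metrics(rep(30, 5), c(20, 25, 30, 35, 40))
  expect_true(is.na(m3$pearson_r))
  expect_false(m3$r_defined)
  # median AE robust to one extreme residual
  base <- clock_metrics(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5) + 1)
  pert <- clock_metrics(c(1, 2, 3, 4, 105), c(1, 2, 3, 4, 5) + 1)
  expect_lt(abs(pert$mae_median - base$mae_median), 100)
})

test_that("noiseless linear signals are recovered by nested CV", {
  set.seed(16)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 45 + 5 * X[, 1] - 3 * X[, 2]
  folds <- assign_age_groups(y, k = 5, seed = 1)
  cv <- nested_cv(X, y, folds, lambda_grid = c(1e-4, 1e-2, 1),
                  alpha_grid = c(0.5))
  expect_gt(cv$pooled$pearson_r, 0.99)
  expect_lt(cv$pooled$rmse, 1)
})

test_that("nested CV never leaks test information", {
  set.seed(17)
  n <- 50
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- 40 + 3 * X[, 1] + rnorm(n)
  folds <- rep(1:5, each = 10)
  cv <- nested_cv(X, y, folds, lambda_grid = c(0.01, 0.1),
                  alpha_grid = 0.5)
  # corrupt the test group's ages: its predictions must not change
  y2 <- y
  y2[folds == 3] <- 0
  cv2 <- nested_cv(X, y2, folds, lambda_grid = c(0.01, 0.1),
                   alpha_grid = 0.5)
  expect_equal(cv$predictions$predicted[folds == 3],
               cv2$predictions$predicted[folds == 3], tolerance = 1e-10)
})

test_that("final model training selects by grouped CV and refits on all data", {
  set.seed(18)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- 45 + 5 * X[, 1]
  folds <- assign_age_groups(y, 5, seed = 2)
  m <- train_final_clock(X, y, folds, lambda_grid = c(1e-4, 1e-2, 1),
                         alpha_grid = 0.5)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 0.5)
  expect_false(is.null(attr(m, "selection")))
})

test_that("multiomic concatenation prefixes ids and preserves shared samples", {
  atac <- matrix(1:6, 3, 2, dimnames = list(paste0("o", 1:3), c("s1", "s2")))
  rna <- matrix(1:4, 2, 2, dimnames = list(paste0("g", 1:2), c("s2", "s3")))
  jm <- concat_multiomic(atac, rna)
  expect_equal(dim(jm), c(5L, 1L))
  expect_equal(rownames(jm), c("atac:o1", "atac:o2", "atac:o3",
                               "rna:g1", "rna:g2"))
  expect_equal(colnames(jm), "s2")
  # empty RNA block leaves an ATAC-only matrix
  jm2 <- concat_multiomic(atac, rna[0, , drop = FALSE])
  expect_equal(nrow(jm2), 3L)
  expect_error(concat_multiomic(atac,
                                matrix(0, 1, 2,
                                       dimnames = list("x", c("s4", "s5")))),
               "no shared samples")
})

test_that("clock models survive a JSON round-trip", {
  set.seed(19)
  X <- matrix(rnorm(100), 10, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(10, 50, 5)
  m <- fit_elastic_net(X, y, 0.2, 0.5)
  path <- tempfile(fileext = ".json")
  save_clock_model(m, path)
  m2 <- load_clock_model(path)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$hyperparams$lambda, 0.2)
})
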