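test_that("PCA matches the dense covariance eigendecomposition oracle", {
  set.seed(101)
  X <- matrix(rnorm(200), 20, 10)
  m <- fit_pca(X, 9)
  Xc <- scale(X, scale = FALSE)
  oracle <- eigen(crossprod(Xc) / 19, symmetric = TRUE)
  expect_equal(m$eigenvalues, oracle$values[1:9], tolerance = 1e-8)
  # loadings span: compare up to sign via absolute inner products
  dots <- abs(rowSums(m$loadings * t(oracle$vectors[, 1:9])))
  expect_equal(dots, rep(1, 9), tolerance = 1e-8)
  # explained variance percentages from the eigenvalues
  expect_equal(m$explained_variance_pct,
               100 * oracle$values[1:9] / sum(oracle$values),
               tolerance = 1e-8)
})

test_that("PCA loadings are orthonormal and reconstruction is exact", {
  set.seed(5)
  X <- matrix(rnorm(15 * 40), 15, 40)
  k <- 14
  m <- fit_pca(X, k)
  G <- m$loadings %*% t(m$loadings)
  expect_lt(max(abs(G - diag(k))), 1e-10)
  sc <- pca_scores(m, X, k)
  rec <- sweep(sc %*% m$loadings, 2, m$mean, `+`)
  expect_lt(max(abs(rec - X)) / max(abs(X)), 1e-10)
})

test_that("PCA on two distinct points explains everything with one component", {
  X <- rbind(c(1, 2, 3), c(3, 2, 1))
  m <- fit_pca(X, 1)
  expect_equal(m$explained_variance_pct, 100, tolerance = 1e-12)
  expect_error(fit_pca(X, 2), "n_components")
})

test_that("PCA agrees with prcomp and both matrix-shape branches agree", {
  set.seed(8)
  X_wide <- matrix(rnorm(12 * 30), 12, 30)   # n < p: Gram branch
  X_tall <- matrix(rnorm(30 * 12), 30, 12)   # n > p: covariance branch
  for (X in list(X_wide, X_tall)) {
    k <- 5
    m <- fit_pca(X, k)
    pr <- prcomp(X, center = TRUE)
    expect_equal(m$eigenvalues, unname(pr$sdev[1:k]^2), tolerance = 1e-8)
    dots <- abs(colSums(t(m$loadings) * pr$rotation[, 1:k]))
    expect_equal(unname(dots), rep(1, k), tolerance = 1e-8)
  }
})

test_that("LDA matches the closed form on a hand-computable 2-D problem", {
  scores <- rbind(c(0, 0), c(2, 0), c(1, 1), c(1, -1),
                  c(5, 0), c(7, 0), c(6, 1), c(6, -1))
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- fit_lda(scores, labels)
  # pooled scatter: each class contributes diag(2, 2); means differ by (5, 0);
  # class means are (1, 0) and (6, 0)
  Sw <- diag(c(4, 4))
  want <- solve(Sw + diag(1e-8 * sum(diag(Sw)) / 2, 2), c(5, 0))
  expect_equal(m$direction, unname(want), tolerance = 1e-10)
  expect_equal(m$threshold, sum(want * c(3.5, 0)), tolerance = 1e-10)
})

test_that("LDA separates 1-D classes and orients toward class 1", {
  set.seed(3)
  scores <- matrix(c(rnorm(30, -1, 0.1), rnorm(30, 1, 0.1)), ncol = 1)
  labels <- rep(c(0, 1), each = 30)
  m <- fit_lda(scores, labels)
  expect_gt(m$direction, 0)
  expect_lt(abs(m$threshold), 0.1)
  pred <- drop(scores %*% m$direction) - m$threshold >= 0
  expect_equal(mean(pred == labels), 1)
  expect_error(fit_lda(scores, rep(0, 60)), "both classes")
})

test_that("full-rank PCA-LDA equals LDA on the raw centred data", {
  set.seed(17)
  X <- matrix(rnorm(40 * 6), 40, 6)
  labels <- rep(c(0, 1), 20)
  X[labels == 1, 2] <- X[labels == 1, 2] + 1
  full <- fit_pca_lda(X, labels, n_pcs = 6)
  d_full <- predict_pca_lda(full, X)
  Xc <- scale(X, scale = FALSE)
  raw <- fit_lda(Xc, labels)
  d_raw <- drop(Xc %*% raw$direction) - raw$threshold
  expect_equal(d_full >= 0, d_raw >= 0)
  # decision values agree up to overall positive scale
  expect_equal(d_full / max(abs(d_full)), d_raw / max(abs(d_raw)),
               tolerance = 1e-6)
})

test_that("PCA-LDA separates noise-free single-band classes perfectly", {
  grid <- seq(400, 1800, by = 4)
  prof <- peak_profile(grid, 1004, 10, "lorentzian")
  base <- peak_profile(grid, 1450, 18, "gaussian")
  X <- rbind(t(replicate(10, base + prof)), t(replicate(10, base + 1.5 * prof)))
  labels <- rep(c(0, 1), each = 10)
  X <- X + matrix(rnorm(length(X), sd = 1e-6), nrow(X))  # break exact ties
  m <- fit_pca_lda(X, labels, n_pcs = 2)
  mm <- compute_metrics(predict_pca_lda(m, X), labels, 0)
  expect_equal(mm$sensitivity, 100)
  expect_equal(mm$specificity, 100)
})

test_that("PLS-DA at full rank reproduces least-squares predictions", {
  set.seed(23)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.1) > 0)
  m <- fit_plsda(X, y, n_lv = p)
  pred <- predict_plsda(m, X)
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  ols <- drop(Xc %*% beta) + mean(y)
  expect_equal(pred, ols, tolerance = 1e-8)
})

test_that("first SIMPLS weight is proportional to X'y", {
  set.seed(29)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- rep(c(0, 1), length.out = 25)
  m <- fit_plsda(X, y, n_lv = 3)
  w1 <- m$weights[1, ]
  s <- drop(crossprod(scale(X, scale = FALSE), y - mean(y)))
  expect_equal(abs(sum(w1 * s)) / (sqrt(sum(w1^2)) * sqrt(sum(s^2))), 1,
               tolerance = 1e-8)
})

test_that("PLS-DA scores are orthogonal and explained variance is monotone", {
  set.seed(31)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(c(0, 1), 20)
  m <- fit_plsda(X, y, n_lv = 5)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_true(all(diff(m$pct_var_x) > -1e-9))
  expect_true(all(diff(m$pct_var_y) > -1e-9))
  expect_lte(max(m$pct_var_x), 100 + 1e-9)
  expect_lte(max(m$pct_var_y), 100 + 1e-9)
})

test_that("noiseless single informative direction is solved by one LV", {
  set.seed(37)
  n <- 24; p <- 15
  direction <- rnorm(p)
  y <- rep(c(0, 1), n / 2)
  X <- outer(y - mean(y), direction)
  m <- fit_plsda(X, y, n_lv = 1)
  expect_equal(m$pct_var_y[1], 100, tolerance = 1e-8)
  mm <- compute_metrics(predict_plsda(m, X), y, 0.5)
  expect_equal(mm$sensitivity, 100)
  expect_equal(mm$specificity, 100)
})

test_that("PLS-DA training squared error never increases with more LVs", {
  # the deflation guarantees monotone training RSS; thresholded 0/1 error can
  # fluctuate on noisy data and is checked only at the endpoints
  set.seed(41)
  for (rep in 1:20) {
    n <- 30; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- as.numeric(rnorm(n) + X[, 1] > 0)
    if (length(unique(y)) < 2) next
    kmax <- 6
    m <- fit_plsda(X, y, kmax)
    rss <- vapply(1:kmax, function(k) {
      sum((predict_plsda(m, X, n_lv = k) - y)^2)
    }, numeric(1))
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("PLS-DA prediction identities hold", {
  set.seed(43)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c(0, 1), 15)
  X[y == 1, ] <- X[y == 1, ] + 0.5
  m <- fit_plsda(X, y, 3)
  # overall training mean predicts the class prevalence
  expect_equal(predict_plsda(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  # duplicate rows get identical predictions
  two <- predict_plsda(m, X[c(4, 4), ])
  expect_identical(two[1], two[2])
  # class-1 centroid lands on the positive side for separable classes
  c1 <- matrix(colMeans(X[y == 1, ]), 1)
  expect_gte(predict_plsda(m, c1), 0.5)
  expect_error(predict_plsda(m, X[, 1:5]), "mismatch")
})

test_that("repeated fits are bit-identical (deterministic algorithms)", {
  set.seed(47)
  X <- matrix(rnorm(25 * 14), 25, 14)
  y <- rep(c(0, 1), length.out = 25)
  expect_identical(fit_plsda(X, y, 4), fit_plsda(X, y, 4))
  expect_identical(fit_pca(X, 5), fit_pca(X, 5))
  expect_identical(fit_pca_lda(X, y, 5), fit_pca_lda(X, y, 5))
})
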