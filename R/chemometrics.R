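# From-scratch chemometric models. PCA is computed from whichever of the two
# symmetric eigenproblems is smaller (the n x n Gram matrix in the usual
# n_spectra << n_wavenumbers regime). Loadings and weights carry a fixed sign
# convention (largest-|element| positive) so fits are bit-reproducible.

fix_sign <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Principal component analysis of a spectral matrix
#'
#' @param X Numeric matrix, one spectrum per row. Centred internally on its
#'   column means (pass an already-centred matrix to reuse a training mean).
#' @param n_components Number of components, at most `min(nrow(X)-1, ncol(X))`.
#' @return An object of class `pca_model`: `mean`, `loadings` (orthonormal,
#'   `n_components x n_points`), `explained_variance_pct` (descending),
#'   `singular_values`.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (n_components < 1 || n_components > kmax) {
    stop("n_components must be in 1..", kmax)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, `-`)
  if (n - 1L <= p) {
    G <- tcrossprod(Xc)                       # n x n
    eg <- eigen(G, symmetric = TRUE)
    d <- pmax(eg$values[seq_len(kmax)], 0)
    keep <- seq_len(n_components)
    V <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])  # p x k
    nz <- sqrt(pmax(d[keep], .Machine$double.eps^2))
    V <- sweep(V, 2, nz, `/`)
  } else {
    C <- crossprod(Xc)                        # p x p
    eg <- eigen(C, symmetric = TRUE)
    d <- pmax(eg$values[seq_len(kmax)], 0)
    V <- eg$vectors[, seq_len(n_components), drop = FALSE]
  }
  V <- apply(V, 2, fix_sign)
  total <- sum(d)
  pct <- if (total > 0) 100 * d[seq_len(n_components)] / total else
    rep(0, n_components)
  structure(list(mean = mu,
                 loadings = t(V),
                 explained_variance_pct = pct,
                 eigenvalues = d[seq_len(n_components)] / (n - 1L)),
            class = "pca_model")
}

#' Project spectra onto principal components
#'
#' @param model A `pca_model`.
#' @param X Matrix with the same column count as the training data.
#' @param n_components Number of leading components (default all fitted).
#' @return Score matrix `nrow(X) x n_components`.
#' @export
pca_scores <- function(model, X, n_components = nrow(model$loadings)) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) stop("column count mismatch")
  k <- n_components
  if (k < 1 || k > nrow(model$loadings)) stop("n_components out of range")
  sweep(X, 2, model$mean, `-`) %*% t(model$loadings[seq_len(k), , drop = FALSE])
}

#' Fisher linear discriminant on score vectors
#'
#' Two-class LDA: direction proportional to `S_w^{-1} (m1 - m0)` with pooled
#' within-class scatter `S_w` (ridge `1e-8 * trace/k` added for near-singular
#' folds), oriented so class-1 projections exceed class-0 projections;
#' threshold at the midpoint of the projected class means.
#'
#' @param scores Numeric matrix `n x k`.
#' @param labels 0/1 vector (1 = positive class, here HSIL).
#' @return An object of class `lda_model`: `direction`, `threshold`,
#'   `class_means_projected`.
#' @export
fit_lda <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  k <- ncol(scores)
  m0 <- colMeans(scores[labels == 0L, , drop = FALSE])
  m1 <- colMeans(scores[labels == 1L, , drop = FALSE])
  Sw <- matrix(0, k, k)
  for (cl in c(0L, 1L)) {
    Z <- sweep(scores[labels == cl, , drop = FALSE], 2,
               if (cl == 0L) m0 else m1, `-`)
    Sw <- Sw + crossprod(Z)
  }
  ridge <- 1e-8 * sum(diag(Sw)) / k
  if (ridge <= 0) ridge <- 1e-12
  w <- solve(Sw + diag(ridge, k), m1 - m0)
  proj0 <- sum(w * m0); proj1 <- sum(w * m1)
  if (proj1 < proj0) { w <- -w; tmp <- proj0; proj0 <- proj1; proj1 <- tmp }
  structure(list(direction = as.numeric(w),
                 threshold = (proj0 + proj1) / 2,
                 class_means_projected = c(`0` = proj0, `1` = proj1)),
            class = "lda_model")
}

#' Fit a PCA-LDA classifier
#'
#' PCA on the (internally centred) spectral matrix followed by Fisher LDA on
#' the leading `n_pcs` score columns.
#'
#' @param X Numeric spectral matrix, one row per spectrum.
#' @param labels 0/1 vector (1 = HSIL).
#' @param n_pcs Number of principal components fed to the LDA.
#' @return An object of class `pcalda_model` with elements `pca`, `lda`,
#'   `n_pcs`.
#' @export
fit_pca_lda <- function(X, labels, n_pcs) {
  pca <- fit_pca(X, n_pcs)
  sc <- pca_scores(pca, X, n_pcs)
  lda <- fit_lda(sc, labels)
  structure(list(pca = pca, lda = lda, n_pcs = as.integer(n_pcs)),
            class = "pcalda_model")
}

#' Decision values of a PCA-LDA classifier
#'
#' @param m A `pcalda_model`.
#' @param X_new Matrix with matching column count.
#' @return Numeric vector of signed decision values (projection minus
#'   threshold); call HSIL iff value >= 0.
#' @export
predict_pca_lda <- function(m, X_new) {
  sc <- pca_scores(m$pca, X_new, m$n_pcs)
  drop(sc %*% m$lda$direction) - m$lda$threshold
}

#' Fit a PLS-DA model (SIMPLS)
#'
#' Partial least squares regression of the 0/1 class coding on the spectra via
#' the SIMPLS algorithm: latent variables maximise covariance with the class
#' membership under orthogonal score constraints. Both blocks are centred
#' internally; explained variance in X and Y is accounted per latent variable
#' from the deflation.
#'
#' @param X Numeric spectral matrix, one row per spectrum.
#' @param y 0/1 class coding (1 = HSIL).
#' @param n_lv Number of latent variables, at most `min(nrow(X)-1, ncol(X))`.
#' @return An object of class `plsda_model`: `x_mean`, `y_mean`, `weights`
#'   (`n_lv x p`), `x_loadings`, `y_loadings`, `regression_vector` (for the
#'   full `n_lv`), `pct_var_x`, `pct_var_y` (cumulative), `n_lv`.
#' @export
fit_plsda <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length must equal nrow(X)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  kmax <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > kmax) stop("n_lv must be in 1..", kmax)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean, `-`)
  yc <- y - y_mean
  ss_x <- sum(Xc^2); ss_y <- sum(yc^2)

  S <- drop(crossprod(Xc, yc))                 # p x 1 cross-covariance
  R <- matrix(0, p, n_lv)   # weights (X-side, applied to centred X)
  P <- matrix(0, p, n_lv)   # X loadings
  Q <- numeric(n_lv)        # y loadings
  V <- matrix(0, p, n_lv)   # orthonormal basis of loading space
  Tm <- matrix(0, n, n_lv)  # orthonormal scores
  for (a in seq_len(n_lv)) {
    r <- S                                     # univariate y: dominant direction
    t <- drop(Xc %*% r)
    t_norm <- sqrt(sum(t^2))
    if (t_norm < .Machine$double.eps * 100) {
      stop("X has rank < n_lv; reduce n_lv")
    }
    t <- t / t_norm; r <- r / t_norm
    pvec <- drop(crossprod(Xc, t))
    q <- sum(yc * t)
    v <- pvec
    if (a > 1) {
      v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], pvec)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v * drop(crossprod(v, S))
    R[, a] <- r; P[, a] <- pvec; Q[a] <- q; V[, a] <- v; Tm[, a] <- t
  }
  sgn <- vapply(seq_len(n_lv), function(a) {
    j <- which.max(abs(R[, a])); if (R[j, a] < 0) -1 else 1
  }, numeric(1))
  R <- sweep(R, 2, sgn, `*`); P <- sweep(P, 2, sgn, `*`)
  Q <- Q * sgn; Tm <- sweep(Tm, 2, sgn, `*`)
  pct_var_x <- 100 * cumsum(colSums(P^2)) / ss_x
  pct_var_y <- 100 * cumsum(Q^2) / ss_y
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 weights = t(R), x_loadings = t(P), y_loadings = Q,
                 scores = Tm,
                 regression_vector = drop(R %*% Q),
                 pct_var_x = pct_var_x, pct_var_y = pct_var_y,
                 n_lv = as.integer(n_lv)),
            class = "plsda_model")
}

#' Predicted class values from a PLS-DA model
#'
#' @param m A `plsda_model`.
#' @param X_new Matrix with matching column count.
#' @param n_lv Number of latent variables to use (default all fitted);
#'   truncation reuses the leading SIMPLS components.
#' @return Numeric vector of continuous predicted values on the 0/1 coding
#'   scale (not clipped); classification happens downstream at a threshold.
#' @export
predict_plsda <- function(m, X_new, n_lv = m$n_lv) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(m$x_mean)) stop("column count mismatch")
  if (n_lv < 1 || n_lv > m$n_lv) stop("n_lv out of fitted range")
  b <- drop(t(m$weights[seq_len(n_lv), , drop = FALSE]) %*%
              m$y_loadings[seq_len(n_lv)])
  drop(sweep(X_new, 2, m$x_mean, `-`) %*% b) + m$y_mean
}
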