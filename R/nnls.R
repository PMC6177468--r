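# Lawson-Hanson active-set solver for min ||y - B c|| s.t. c >= 0.
# Deterministic: the entering variable is the smallest index attaining the
# maximal positive gradient, so runs are bit-reproducible and duplicated
# columns resolve to the smallest-index component.

#' Non-negative least squares against a basis set
#'
#' Solves `argmin ||y - B c||_2` subject to `c >= 0` with the Lawson-Hanson
#' active-set algorithm. At the solution the Karush-Kuhn-Tucker conditions
#' hold: the residual is orthogonal to every component with a positive
#' coefficient and has non-positive inner product with every clamped one.
#'
#' @param y Numeric intensity vector.
#' @param basis A `basis_set` on the same axis, or a numeric matrix with one
#'   column per component.
#' @param tol Gradient tolerance for termination (relative to
#'   `max|B^T y|`).
#' @return Named numeric vector of coefficients, one per component.
#' @export
nnls_fit <- function(y, basis, tol = 1e-10) {
  B <- if (inherits(basis, "basis_set")) {
    if (length(y) != length(basis$wavenumbers)) {
      stop("y and basis must share one axis")
    }
    basis$components
  } else as.matrix(basis)
  if (nrow(B) != length(y)) stop("y and basis must share one axis")
  p <- ncol(B)
  dup <- duplicated(t(B))
  if (any(dup)) {
    warning("basis contains identical components; the smallest-index one is used")
  }
  coef <- numeric(p)
  passive <- logical(p)
  resid <- y
  scale <- max(abs(crossprod(B, y)), .Machine$double.eps)
  max_outer <- 3L * p + 30L
  for (outer_it in seq_len(max_outer)) {
    grad <- drop(crossprod(B, resid))
    grad[passive] <- -Inf
    j <- which.max(grad)          # ties -> smallest index
    if (grad[j] <= tol * scale) break
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- solve_ls_subset(B[, idx, drop = FALSE], y)
      if (all(z > 0)) {
        coef[] <- 0; coef[idx] <- z
        break
      }
      neg <- z <= 0
      ratios <- coef[idx][neg] / (coef[idx][neg] - z[neg])
      ratios[!is.finite(ratios)] <- 0
      alpha <- min(ratios)
      coef[idx] <- coef[idx] + alpha * (z - coef[idx])
      passive[idx][coef[idx] <= .Machine$double.eps * 10] <- FALSE
      coef[!passive] <- 0
    }
    resid <- y - drop(B %*% coef)
  }
  names(coef) <- colnames(B)
  coef
}

# Least squares on a column subset; rank-deficient subsets are resolved via
# the QR pivot (dependent columns get coefficient 0 -> smallest-index
# component preferred because duplicates enter later).
solve_ls_subset <- function(Bs, y) {
  qr_ <- qr(Bs)
  z <- qr.coef(qr_, y)
  z[is.na(z)] <- 0
  z
}

#' Subtract the fitted background from a spectrum
#'
#' Removes only the background-flagged components scaled by their fitted
#' coefficients; biochemical components stay in the spectrum (their role in
#' the fit is to stabilise the glass coefficient, not to denoise).
#'
#' @param y A `raman_spectrum` or numeric vector.
#' @param basis A `basis_set`.
#' @param coeffs Coefficients from [nnls_fit()] on `y`.
#' @return Same type as `y`, background removed.
#' @export
subtract_background <- function(y, basis, coeffs) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(coeffs) != ncol(basis$components)) {
    stop("need one coefficient per basis component")
  }
  bg <- drop(basis$components[, basis$background, drop = FALSE] %*%
               coeffs[basis$background])
  if (inherits(y, "raman_spectrum")) {
    raman_spectrum(y$wavenumbers, y$intensities - bg, y$id)
  } else {
    y - bg
  }
}
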