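# Preprocessing chain for raw single-cell spectra measured on glass:
# NNLS glass-background removal -> baseline correction -> vector
# normalization. Mean-centering is deliberately not part of this chain: it is
# applied inside model fitting so that cross-validation can centre each
# training fold on its own mean.

#' Configure the preprocessing chain
#'
#' @param basis A `basis_set` of glass plus biochemical references.
#' @param baseline_method `"rubberband"` (lower convex hull, default) or
#'   `"polynomial"` (iteratively reweighted polynomial fit).
#' @param baseline_poly_degree Polynomial degree (used iff
#'   `baseline_method = "polynomial"`).
#' @param normalize Scale each spectrum to unit L2 norm (default `TRUE`).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(basis,
                              baseline_method = c("rubberband", "polynomial"),
                              baseline_poly_degree = 5,
                              normalize = TRUE) {
  stopifnot(inherits(basis, "basis_set"), baseline_poly_degree >= 0)
  structure(list(basis = basis,
                 baseline_method = match.arg(baseline_method),
                 baseline_poly_degree = as.integer(baseline_poly_degree),
                 normalize = isTRUE(normalize)),
            class = "preprocess_config")
}

# Andrew's monotone-chain lower convex hull; x strictly increasing.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- hull[m - 1L]; b <- hull[m]
      # keep b only if it lies strictly below the chord a->i
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross > 0) break
      m <- m - 1L
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

#' Estimate and subtract the baseline of a spectrum
#'
#' `rubberband`: subtracts the linear interpolant of the lower convex hull of
#' `(wavenumber, intensity)` — an affine spectrum maps to zero.
#' `polynomial`: iteratively reweighted least-squares polynomial of the
#' configured degree; points above the current fit are excluded on the next
#' iteration, until the fit changes by less than `tol` (relative) or 50
#' iterations.
#'
#' @param y A `raman_spectrum` or numeric vector (then `wavenumbers` must be
#'   given).
#' @param cfg A `preprocess_config` (only the baseline fields are used).
#' @param wavenumbers Axis when `y` is a bare vector.
#' @param tol Convergence tolerance of the polynomial method.
#' @return Same type as `y`, baseline removed; attribute `"baseline"` carries
#'   the subtracted vector.
#' @export
baseline_correct <- function(y, cfg, wavenumbers = NULL, tol = 1e-6) {
  is_spec <- inherits(y, "raman_spectrum")
  w <- if (is_spec) y$wavenumbers else as.numeric(wavenumbers)
  v <- if (is_spec) y$intensities else as.numeric(y)
  if (is.null(w)) stop("wavenumbers required for vector input")
  if (length(v) < 3) stop("baseline correction needs at least 3 points")
  bl <- if (cfg$baseline_method == "rubberband") {
    idx <- lower_hull_indices(w, v)
    stats::approx(w[idx], v[idx], xout = w, method = "linear",
                  ties = "ordered")$y
  } else {
    deg <- cfg$baseline_poly_degree
    if (deg >= length(v)) stop("polynomial degree must be < number of points")
    u <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
    X <- outer(u, 0:deg, `^`)
    # modified-polynomial baseline with automatic peak suppression: after each
    # fit, points more than one residual RMS above the fit are clipped to
    # fit + RMS, so peaks progressively lose their pull while baseline points
    # (within noise of the fit) keep theirs; iterate until the residual RMS
    # stabilises
    target <- v
    fit <- rep(0, length(v))
    dev_prev <- Inf
    for (it in seq_len(50L)) {
      cf <- qr.coef(qr(X), target)
      cf[is.na(cf)] <- 0
      fit <- drop(X %*% cf)
      dev <- sqrt(mean((target - fit)^2))
      target <- pmin(target, fit + dev)
      if (is.finite(dev_prev) &&
          abs(dev - dev_prev) < tol * max(dev_prev, 1e-12)) break
      dev_prev <- dev
    }
    fit
  }
  out <- v - bl
  if (is_spec) {
    res <- raman_spectrum(w, out, y$id)
    attr(res, "baseline") <- bl
    res
  } else {
    attr(out, "baseline") <- bl
    out
  }
}

#' Scale a spectrum to unit Euclidean norm
#'
#' @param y A `raman_spectrum` or numeric vector.
#' @return Same type as `y` with `||y||_2 = 1`; attribute `"norm"` carries the
#'   original norm. A zero vector is an error (empty or failed measurement).
#' @export
vector_normalize <- function(y) {
  v <- if (inherits(y, "raman_spectrum")) y$intensities else as.numeric(y)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot normalize a zero spectrum")
  out <- v / nrm
  if (inherits(y, "raman_spectrum")) {
    res <- raman_spectrum(y$wavenumbers, out, y$id)
    attr(res, "norm") <- nrm
    res
  } else {
    attr(out, "norm") <- nrm
    out
  }
}

#' Column mean-centre a spectral matrix
#'
#' With `mean = NULL` the per-wavenumber mean over rows is computed and
#' subtracted; passing a stored training mean centres new (test-fold) rows
#' without touching them during its computation, which makes training/test
#' leakage structurally impossible.
#'
#' @param X Numeric matrix, one spectrum per row.
#' @param mean Optional stored mean vector of length `ncol(X)`.
#' @return List with `matrix` (centred) and `mean` (the vector subtracted).
#' @export
mean_center <- function(X, mean = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("need at least one row")
  if (is.null(mean)) mean <- colMeans(X)
  if (length(mean) != ncol(X)) stop("mean length must equal column count")
  list(matrix = sweep(X, 2, mean, `-`), mean = as.numeric(mean))
}

#' Run the full preprocessing chain on a dataset
#'
#' Per spectrum, in order: NNLS fit against the basis, subtraction of the
#' background-flagged components, baseline correction, vector normalization.
#' All intermediates are retained in the returned record.
#'
#' @param ds A `spectral_dataset` (axis must match the basis axis).
#' @param cfg A [preprocess_config()].
#' @return List with `dataset` (preprocessed `spectral_dataset`) and `record`
#'   (class `preprocess_record`: NNLS coefficient matrix, baseline matrix,
#'   normalization factors).
#' @export
run_preprocess <- function(ds, cfg) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "preprocess_config"))
  basis <- cfg$basis
  if (length(ds$wavenumbers) != length(basis$wavenumbers) ||
      any(abs(ds$wavenumbers - basis$wavenumbers) > 1e-9)) {
    stop("dataset and basis must share one wavenumber axis")
  }
  n <- n_spectra(ds)
  p <- length(ds$wavenumbers)
  coefs <- matrix(0, n, ncol(basis$components),
                  dimnames = list(ds$meta$spectrum_id, colnames(basis$components)))
  baselines <- matrix(0, n, p)
  norms <- numeric(n)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    sid <- ds$meta$spectrum_id[i]
    y <- ds$intensities[i, ]
    stage <- "nnls_fit"
    res <- tryCatch({
      cf <- nnls_fit(y, basis)
      coefs[i, ] <- cf
      stage <- "subtract_background"
      y1 <- subtract_background(y, basis, cf)
      stage <- "baseline_correct"
      y2 <- baseline_correct(y1, cfg, wavenumbers = ds$wavenumbers)
      baselines[i, ] <- attr(y2, "baseline")
      stage <- "vector_normalize"
      if (cfg$normalize) {
        y3 <- vector_normalize(as.numeric(y2))
        norms[i] <- attr(y3, "norm")
        as.numeric(y3)
      } else {
        norms[i] <- 1
        as.numeric(y2)
      }
    }, error = function(e) {
      stop("preprocessing failed for spectrum '", sid, "' at stage ", stage,
           ": ", conditionMessage(e), call. = FALSE)
    })
    out[i, ] <- res
  }
  record <- structure(list(nnls_coefficients = coefs, baselines = baselines,
                           normalization_factors =
                             stats::setNames(norms, ds$meta$spectrum_id),
                           config = cfg),
                      class = "preprocess_record")
  list(dataset = spectral_dataset(ds$wavenumbers, out, ds$meta),
       record = record)
}
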