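# Shared fixture builders. Everything is generated in code; no stored data.

tiny_meta <- function(n, classes = NULL, types = NULL, patients = NULL) {
  cell_meta(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    patient_id = patients %||% sprintf("p%02d", rep_len(1:4, n)),
    cytology_class = classes %||% rep_len(c("negative", "HSIL"), n),
    cell_type = types %||% rep_len(c("intermediate", "superficial"), n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_dataset <- function(n = 4, p = 10, seed = 1, axis = NULL, mat = NULL,
                         ...) {
  axis <- axis %||% seq(400, length.out = p, by = 10)
  if (is.null(mat)) {
    mat <- withr::with_seed(seed, matrix(rnorm(n * length(axis)), n))
  }
  spectral_dataset(axis, mat, tiny_meta(nrow(mat), ...))
}

# Exhaustive active-set oracle for NNLS with <= 3 components: solve the
# unconstrained least-squares problem on every subset of components, keep the
# feasible (all-nonnegative) solution with the smallest residual norm.
nnls_enumeration_oracle <- function(y, B) {
  p <- ncol(B)
  best <- list(coef = numeric(p), rss = sum(y^2))
  subsets <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (s in subsets) {
    z <- tryCatch(qr.coef(qr(B[, s, drop = FALSE]), y),
                  error = function(e) NULL)
    if (is.null(z) || anyNA(z) || any(z < 0)) next
    r <- y - B[, s, drop = FALSE] %*% z
    rss <- sum(r^2)
    if (rss < best$rss - 1e-12) {
      coef <- numeric(p); coef[s] <- z
      best <- list(coef = coef, rss = rss)
    }
  }
  best$coef
}

# Small balanced zero-effect configuration used by null-calibration checks:
# classes identical by construction, i.i.d. spectra (no patient effects), no
# glass or baseline so the t-test independence assumptions hold.
null_config <- function(seed, n_per_stratum = 24, grid = seq(400, 1800, by = 4),
                        patient_sd = 0, noise_sd = 0.02) {
  synthetic_config(
    n_patients_per_class = c(negative = 6, HSIL = 6),
    strata_counts = c(intermediate_negative = n_per_stratum,
                      intermediate_HSIL = n_per_stratum,
                      superficial_negative = n_per_stratum,
                      superficial_HSIL = n_per_stratum),
    class_effects = data.frame(center = numeric(0),
                               relative_change = numeric(0)),
    cell_type_effects = data.frame(center = numeric(0),
                                   relative_change = numeric(0)),
    patient_sd = patient_sd, noise_sd = noise_sd,
    glass_coeff_range = c(0, 0), baseline_coeff_sd = 0,
    grid = grid, seed = seed)
}

# Scaled-down default-regime configuration (all default effects, reduced
# sample size and grid) for the structural-property checks.
scaled_default_config <- function(seed, scale = 3.8,
                                  grid = seq(400, 1800, by = 4)) {
  synthetic_config(
    n_patients_per_class = c(negative = 8, HSIL = 8),
    strata_counts = round(c(intermediate_negative = 176,
                            intermediate_HSIL = 252,
                            superficial_negative = 174,
                            superficial_HSIL = 153) / scale),
    grid = grid, seed = seed)
}
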