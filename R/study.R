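# Study-level result surfaces: group mean +/- SD spectra, difference spectra,
# per-wavenumber two-sample t-tests reduced to a band list, and the full
# three-subset (intermediate / superficial / mixed) classification report.

#' Pointwise mean and SD spectra per group
#'
#' @param ds A `spectral_dataset`.
#' @param by Metadata columns to group by (default `"cytology_class"`).
#' @return List of class `group_summary`: one element per group with `key`,
#'   `n`, `mean`, `sd` (sample SD, denominator n-1; a singleton group gets
#'   SD 0 with a warning) and the shared `wavenumbers`.
#' @export
group_summary <- function(ds, by = "cytology_class") {
  stopifnot(all(by %in% names(ds$meta)))
  key <- interaction(ds$meta[, by, drop = FALSE], drop = TRUE, sep = "/")
  out <- lapply(levels(key), function(k) {
    rows <- which(key == k)
    M <- ds$intensities[rows, , drop = FALSE]
    mu <- colMeans(M)
    sdv <- if (length(rows) > 1) {
      sqrt(colSums(sweep(M, 2, mu, `-`)^2) / (length(rows) - 1))
    } else {
      warning("group '", k, "' has a single spectrum; SD reported as 0")
      rep(0, ncol(M))
    }
    list(key = k, n = length(rows), mean = mu, sd = sdv)
  })
  names(out) <- levels(key)
  structure(list(groups = out, wavenumbers = ds$wavenumbers, by = by),
            class = "group_summary")
}

#' Difference spectrum between two group summaries
#'
#' Difference of group means with a pointwise uncertainty band computed as the
#' root sum of squares of the two group SDs.
#'
#' @param gA,gB Single group entries (elements of `group_summary$groups`).
#' @param wavenumbers Shared axis (for validation only).
#' @return List with `difference` (`meanA - meanB`) and `band`
#'   (`sqrt(sdA^2 + sdB^2)`).
#' @export
difference_spectrum <- function(gA, gB, wavenumbers = NULL) {
  if (length(gA$mean) != length(gB$mean)) stop("groups are not on one axis")
  list(difference = gA$mean - gB$mean,
       band = sqrt(gA$sd^2 + gB$sd^2))
}

#' Per-wavenumber two-sample t-test band detection
#'
#' At every grid point an unpaired two-sided pooled-variance Student t-test
#' compares HSIL against negative spectra. Points with `p < alpha` are merged
#' into contiguous runs and each run is reported at its maximum-|t|
#' wavenumber. No multiple-testing correction is applied to the detection
#' rule; a Bonferroni-adjusted p value is carried alongside for transparency.
#' Points where the pooled variance is zero are flagged and given p = 1.
#'
#' @param ds A `spectral_dataset` with both classes (each n >= 2).
#' @param alpha Pointwise significance level (default 0.001).
#' @return List of class `band_hits`: `bands` (data.frame `wavenumber`, `t`,
#'   `p`, `p_bonferroni`, `run_start`, `run_end`), `pointwise` (per-grid-point
#'   `t`, `p`, `significant`, `degenerate`), `alpha`.
#' @export
differential_bands <- function(ds, alpha = 0.001) {
  y <- cv_class_labels(ds$meta)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2 || n0 < 2) stop("both classes need at least 2 spectra")
  X1 <- ds$intensities[y == 1L, , drop = FALSE]
  X0 <- ds$intensities[y == 0L, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- colSums(sweep(X1, 2, m1, `-`)^2) / (n1 - 1)
  v0 <- colSums(sweep(X0, 2, m0, `-`)^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  degenerate <- se == 0
  tval <- ifelse(degenerate, 0, (m1 - m0) / se)
  df <- n1 + n0 - 2
  pval <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tval), df))
  sig <- pval < alpha
  p_bonf <- pmin(1, pval * length(pval))

  bands <- data.frame(wavenumber = numeric(0), t = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), run_start = numeric(0),
                      run_end = numeric(0))
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      j <- idx[which.max(abs(tval[idx]))]
      bands <- rbind(bands, data.frame(
        wavenumber = ds$wavenumbers[j], t = tval[j], p = pval[j],
        p_bonferroni = p_bonf[j],
        run_start = ds$wavenumbers[starts[k]],
        run_end = ds$wavenumbers[ends[k]]))
    }
  }
  structure(list(bands = bands,
                 pointwise = data.frame(wavenumber = ds$wavenumbers, t = tval,
                                        p = pval, significant = sig,
                                        degenerate = degenerate),
                 alpha = alpha),
            class = "band_hits")
}

study_subsets <- function(ds) {
  list(intermediate = which(ds$meta$cell_type == "intermediate"),
       superficial = which(ds$meta$cell_type == "superficial"),
       mixed = seq_len(n_spectra(ds)))
}

#' Run the full study analysis on a labelled dataset
#'
#' Preprocesses once, then for each of the three subsets (intermediate cells,
#' superficial cells, mixed) computes group summaries, the HSIL-minus-negative
#' difference spectrum, significant bands, and cross-validated PCA-LDA and
#' PLS-DA models with component counts selected by minimum CV error.
#'
#' @param ds A raw `spectral_dataset` with both classes and both cell types.
#' @param basis A `basis_set` for glass correction.
#' @param cv A [cv_config()].
#' @param candidates Candidate component counts for both model families.
#' @param alpha Pointwise significance level for band detection.
#' @param preprocess A [preprocess_config()]; defaults to rubberband baseline
#'   with the given basis.
#' @return An object of class `study_report`: per-subset summaries,
#'   differences, `band_hits`, and `cv_report`s for `plsda` and `pcalda`;
#'   plus the `preprocess_record` and the configuration used. A subset whose
#'   cell type is absent is skipped with a warning.
#' @export
run_study <- function(ds, basis, cv, candidates = 1:10, alpha = 0.001,
                      preprocess = preprocess_config(basis)) {
  pp <- run_preprocess(ds, preprocess)
  pds <- pp$dataset
  subsets <- study_subsets(pds)
  results <- list()
  for (nm in names(subsets)) {
    rows <- subsets[[nm]]
    if (!length(rows)) {
      warning("subset '", nm, "' is empty; skipped")
      next
    }
    sub <- subset_dataset(pds, rows)
    if (length(unique(sub$meta$cytology_class)) < 2) {
      warning("subset '", nm, "' lacks a class; skipped")
      next
    }
    gs <- group_summary(sub, "cytology_class")
    diffs <- difference_spectrum(gs$groups[["HSIL"]], gs$groups[["negative"]])
    bands <- differential_bands(sub, alpha)
    reports <- list(
      plsda = cross_validate(sub, "plsda", candidates, cv),
      pcalda = cross_validate(sub, "pcalda", candidates, cv)
    )
    # final full-subset PLS-DA at the CV-chosen count, for loadings and the
    # explained-variance accounting reported alongside the metrics
    final_plsda <- fit_plsda(sub$intensities,
                             cv_class_labels(sub$meta),
                             reports$plsda$chosen_components)
    results[[nm]] <- list(summary = gs, difference = diffs, bands = bands,
                          models = reports, final_plsda = final_plsda,
                          n = length(rows))
  }
  structure(list(subsets = results, preprocess_record = pp$record,
                 cv_config = cv, candidates = candidates, alpha = alpha),
            class = "study_report")
}

#' Flat metrics table from a study report
#'
#' @param report A `study_report`.
#' @return A `data.frame` with one row per subset x model: chosen components,
#'   sensitivity, specificity, confusion counts and (for PLS-DA) cumulative
#'   explained variance at the chosen count.
#' @export
study_metrics_table <- function(report) {
  rows <- list()
  for (nm in names(report$subsets)) {
    res <- report$subsets[[nm]]
    for (mod in names(res$models)) {
      r <- res$models[[mod]]
      m <- r$metrics
      k <- r$chosen_components
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, model = mod, n = res$n,
        n_components = k,
        sensitivity = m$sensitivity, specificity = m$specificity,
        tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
        cv_error = min(r$curve$error),
        pct_var_x = if (mod == "plsda") res$final_plsda$pct_var_x[k] else
          NA_real_,
        pct_var_y = if (mod == "plsda") res$final_plsda$pct_var_y[k] else
          NA_real_)
    }
  }
  do.call(rbind, rows)
}
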