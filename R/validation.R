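# Random-subsets cross-validation: per iteration the units (spectra, or
# patients to avoid within-patient leakage) are randomly partitioned into
# n_splits disjoint test sets of near-equal size, so every unit is tested
# exactly once per iteration; the whole procedure is repeated n_iterations
# times and per-spectrum predictions are averaged across iterations.

#' Configure random-subsets cross-validation
#'
#' @param n_splits Number of disjoint test subsets per iteration (default 20).
#' @param n_iterations Number of repeated random partitions (default 10).
#' @param grouping Unit of partitioning: `"spectrum"` (default, matches a
#'   samples/20 split of the spectra) or `"patient"` (no patient appears in
#'   both training and test of any fold; recommended when patient-level
#'   correlation matters).
#' @param seed Mandatory integer seed.
#' @param center_before_cv Centre the full matrix once before splitting
#'   (global-centring order) instead of centring each training fold; default
#'   `FALSE` (fold-wise centring, no leakage of test-fold means).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_splits = 20, n_iterations = 10,
                      grouping = c("spectrum", "patient"), seed = NULL,
                      center_before_cv = FALSE) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(n_splits >= 2, n_iterations >= 1)
  structure(list(n_splits = as.integer(n_splits),
                 n_iterations = as.integer(n_iterations),
                 grouping = match.arg(grouping), seed = as.integer(seed),
                 center_before_cv = isTRUE(center_before_cv)),
            class = "cv_config")
}

# One random partition of `units` into n_splits test sets, sizes differing by
# at most 1, using the current RNG stream.
partition_units <- function(units, n_splits) {
  n <- length(units)
  if (n < n_splits) stop("need at least n_splits units (", n_splits,
                         "), got ", n)
  shuffled <- sample(units)
  sizes <- rep(n %/% n_splits, n_splits)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  split(shuffled, rep(seq_len(n_splits), sizes))
}

#' Random-subsets partitions
#'
#' For each iteration, a random partition of the unit ids into `n_splits`
#' disjoint test sets whose sizes differ by at most one and whose union is all
#' units. Reproducible from `cfg$seed`; iteration `k` depends only on the seed
#' and `k`, so growing `n_iterations` never changes earlier iterations.
#'
#' @param units Character or integer vector of unit ids (spectrum or patient
#'   ids).
#' @param cfg A [cv_config()].
#' @return List (one element per iteration) of lists of test-set id vectors.
#' @export
make_random_subsets <- function(units, cfg) {
  stopifnot(inherits(cfg, "cv_config"))
  lapply(seq_len(cfg$n_iterations), function(it) {
    with_seed(derive_seed(cfg$seed, it), partition_units(units, cfg$n_splits))
  })
}

#' Smallest component count minimising the cross-validation error
#'
#' @param curve A `data.frame`/list with `n_components` and `error` (mean CV
#'   misclassification per candidate), as found in a `cv_report`.
#' @return The smallest candidate achieving the minimum error.
#' @export
select_components <- function(curve) {
  if (!length(curve$error)) stop("empty CV curve")
  as.integer(curve$n_components[which.min(curve$error)])
}

#' Sensitivity/specificity from per-spectrum predictions
#'
#' Calls HSIL iff `predicted >= threshold` (exact ties count as positive) and
#' tallies the confusion matrix. Sensitivity is the percentage of HSIL spectra
#' called HSIL, specificity the percentage of negative spectra called
#' negative.
#'
#' @param predicted Numeric vector of predicted values.
#' @param labels 0/1 vector (1 = HSIL).
#' @param threshold Decision threshold.
#' @return List of class `diagnostic_metrics`: `sensitivity`, `specificity`
#'   (percent), `threshold`, and counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(predicted, labels, threshold) {
  labels <- as.integer(labels)
  if (length(predicted) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  call_pos <- predicted >= threshold
  tp <- sum(call_pos & labels == 1L)
  fn <- sum(!call_pos & labels == 1L)
  tn <- sum(!call_pos & labels == 0L)
  fp <- sum(call_pos & labels == 0L)
  structure(list(sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "diagnostic_metrics")
}

cv_class_labels <- function(meta) as.integer(meta$cytology_class == "HSIL")

#' Cross-validate a classifier over candidate component counts
#'
#' For each iteration and fold, the model is fitted on the training fold
#' (centred on the training fold only) and the held-out spectra are predicted
#' at every candidate component count. Per-spectrum predictions are averaged
#' over iterations; the component count is chosen by minimum mean CV
#' misclassification error (ties broken toward fewer components) and
#' diagnostic metrics are computed from the averaged predictions at the
#' chosen count.
#'
#' If a random partition leaves a training fold with a single class it is
#' redrawn (at most 100 attempts).
#'
#' @param ds A preprocessed `spectral_dataset` containing both classes.
#' @param model `"plsda"` or `"pcalda"`.
#' @param candidates Integer vector of candidate component counts.
#' @param cfg A [cv_config()].
#' @return An object of class `cv_report`: `curve` (`n_components`, `error`),
#'   `chosen_components`, `predictions` (per spectrum, averaged over
#'   iterations, at the chosen count), `prediction_matrix` (per candidate),
#'   `metrics`, `threshold`, `model`, `grouping`, `config`.
#' @export
cross_validate <- function(ds, model = c("plsda", "pcalda"),
                           candidates = 1:10, cfg) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "cv_config"))
  candidates <- sort(unique(as.integer(candidates)))
  y <- cv_class_labels(ds$meta)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- ds$intensities
  if (cfg$center_before_cv) X <- mean_center(X)$matrix
  n <- nrow(X)
  kmax <- max(candidates)
  threshold <- if (model == "plsda") 0.5 else 0
  units <- if (cfg$grouping == "patient") unique(ds$meta$patient_id) else
    ds$meta$spectrum_id
  rows_of <- function(test_units) {
    if (cfg$grouping == "patient") which(ds$meta$patient_id %in% test_units)
    else which(ds$meta$spectrum_id %in% test_units)
  }

  pred_sum <- matrix(0, n, length(candidates))
  err_sum <- matrix(0, cfg$n_iterations, length(candidates))
  for (it in seq_len(cfg$n_iterations)) {
    it_pred <- with_seed(derive_seed(cfg$seed, it), {
      folds <- NULL
      for (attempt in seq_len(100L)) {
        cand <- partition_units(units, cfg$n_splits)
        ok <- all(vapply(cand, function(ts) {
          length(unique(y[-rows_of(ts)])) == 2L
        }, logical(1)))
        if (ok) { folds <- cand; break }
      }
      if (is.null(folds)) {
        stop("could not draw a partition with both classes in every ",
             "training fold")
      }
      it_pred <- matrix(NA_real_, n, length(candidates))
      for (ts in folds) {
        test <- rows_of(ts)
        train <- setdiff(seq_len(n), test)
        fold_kmax <- min(kmax, length(train) - 1L, ncol(X))
        if (fold_kmax < kmax) {
          stop("candidate component count ", kmax,
               " exceeds training fold capacity ", fold_kmax)
        }
        if (model == "plsda") {
          fit <- fit_plsda(X[train, , drop = FALSE], y[train], kmax)
          for (ci in seq_along(candidates)) {
            it_pred[test, ci] <- predict_plsda(fit, X[test, , drop = FALSE],
                                               n_lv = candidates[ci])
          }
        } else {
          pca <- fit_pca(X[train, , drop = FALSE], kmax)
          sc_train <- pca_scores(pca, X[train, , drop = FALSE], kmax)
          sc_test <- pca_scores(pca, X[test, , drop = FALSE], kmax)
          for (ci in seq_along(candidates)) {
            k <- candidates[ci]
            lda <- fit_lda(sc_train[, seq_len(k), drop = FALSE], y[train])
            it_pred[test, ci] <-
              drop(sc_test[, seq_len(k), drop = FALSE] %*% lda$direction) -
              lda$threshold
          }
        }
      }
      it_pred
    })
    stopifnot(!anyNA(it_pred))  # every spectrum predicted exactly once
    pred_sum <- pred_sum + it_pred
    err_sum[it, ] <- colMeans((it_pred >= threshold) != y)
  }
  pred_mean <- pred_sum / cfg$n_iterations
  curve <- data.frame(n_components = candidates, error = colMeans(err_sum))
  chosen <- select_components(curve)
  predictions <- stats::setNames(pred_mean[, match(chosen, candidates)],
                                 ds$meta$spectrum_id)
  metrics <- compute_metrics(predictions, y, threshold)
  structure(list(curve = curve, chosen_components = chosen,
                 predictions = predictions,
                 prediction_matrix = `colnames<-`(
                   pred_mean, paste0("k", candidates)),
                 metrics = metrics, threshold = threshold, model = model,
                 grouping = cfg$grouping, config = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, grouping=%s: %d components (min CV error %.3f)\n",
              x$model, x$grouping, x$chosen_components, min(x$curve$error)))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%% at threshold %g\n",
              x$metrics$sensitivity, x$metrics$specificity, x$threshold))
  invisible(x)
}
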