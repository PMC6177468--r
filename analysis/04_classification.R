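#!/usr/bin/env Rscript
# Step 4: cross-validated PCA-LDA and PLS-DA classification.
#
# Random-subsets cross-validation (20 disjoint test sets per iteration, 10
# iterations) on each subset; component counts (PCs / latent variables)
# chosen by minimum cross-validation error; per-spectrum predictions averaged
# over iterations; sensitivity and specificity computed at the 0/1-coding
# midpoint threshold (0.5 for PLS-DA, 0 for the signed PCA-LDA decision
# value).

suppressPackageStartupMessages(library(ramancyto))

in_path <- "results/data/raman_study_preprocessed.csv"
out_dir <- "results/tables"
if (!file.exists(in_path)) stop("run analysis/02_preprocess.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ds <- read_dataset(in_path)
cv <- cv_config(n_splits = 20, n_iterations = 10, seed = 202)
candidates <- 1:8

subsets <- list(
  intermediate = ds$meta$cell_type == "intermediate",
  superficial = ds$meta$cell_type == "superficial",
  mixed = rep(TRUE, n_spectra(ds))
)

metrics <- list(); curves <- list(); preds <- list()
for (nm in names(subsets)) {
  sub <- subset_dataset(ds, subsets[[nm]])
  for (model in c("plsda", "pcalda")) {
    r <- cross_validate(sub, model, candidates, cv)
    cat(sprintf("%-13s %-6s: %d components, sens %.1f%%, spec %.1f%%\n",
                nm, model, r$chosen_components,
                r$metrics$sensitivity, r$metrics$specificity))
    metrics[[paste(nm, model)]] <- data.frame(
      subset = nm, model = model, n = n_spectra(sub),
      n_components = r$chosen_components,
      sensitivity = r$metrics$sensitivity,
      specificity = r$metrics$specificity,
      tp = r$metrics$tp, fp = r$metrics$fp,
      tn = r$metrics$tn, fn = r$metrics$fn)
    curves[[paste(nm, model)]] <- data.frame(
      subset = nm, model = model, r$curve)
    preds[[paste(nm, model)]] <- data.frame(
      subset = nm, model = model,
      spectrum_id = names(r$predictions),
      cytology_class = sub$meta$cytology_class,
      cell_type = sub$meta$cell_type,
      predicted = unname(r$predictions))
  }
  # explained variance of the final full-subset PLS-DA at the chosen count
  y <- as.integer(sub$meta$cytology_class == "HSIL")
  k <- metrics[[paste(nm, "plsda")]]$n_components
  fit <- fit_plsda(sub$intensities, y, k)
  cat(sprintf("              PLS-DA %d LV: %.1f%% X-variance, %.1f%% Y-variance\n",
              k, fit$pct_var_x[k], fit$pct_var_y[k]))
}

utils::write.csv(do.call(rbind, metrics),
                 file.path(out_dir, "classification_metrics.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, curves),
                 file.path(out_dir, "cv_error_curves.csv"), row.names = FALSE)
utils::write.csv(do.call(rbind, preds),
                 file.path(out_dir, "cv_predictions.csv"), row.names = FALSE)
cat("Wrote metrics, CV curves and per-spectrum predictions to", out_dir, "\n")
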