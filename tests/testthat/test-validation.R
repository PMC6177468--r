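test_that("random-subsets partitions are disjoint, covering and balanced", {
  cfg <- cv_config(n_splits = 20, n_iterations = 3, seed = 2)
  units <- sprintf("u%03d", 1:100)
  parts <- make_random_subsets(units, cfg)
  expect_length(parts, 3)
  for (it in parts) {
    expect_length(it, 20)
    expect_true(all(lengths(it) == 5))
    expect_setequal(unlist(it), units)
    expect_identical(anyDuplicated(unlist(it)), 0L)
  }
})

test_that("partition property sweep: sizes within 1, disjoint, covering", {
  for (n in c(21, 57, 100, 755)) {
    for (splits in c(2, 7, 20)) {
      for (seed in c(1, 99)) {
        cfg <- cv_config(n_splits = splits, n_iterations = 1, seed = seed)
        part <- make_random_subsets(seq_len(n), cfg)[[1]]
        sizes <- lengths(part)
        expect_lte(max(sizes) - min(sizes), 1)
        expect_identical(sort(unname(unlist(part))), seq_len(n))
      }
    }
  }
  # the study-scale case: 755 units in 20 splits -> sizes 37 or 38
  cfg <- cv_config(n_splits = 20, n_iterations = 1, seed = 4)
  sizes <- lengths(make_random_subsets(1:755, cfg)[[1]])
  expect_setequal(unique(sizes), c(37L, 38L))
})

test_that("partitions are seed-deterministic and iteration-stable", {
  u <- sprintf("u%02d", 1:40)
  a <- make_random_subsets(u, cv_config(n_splits = 5, n_iterations = 2, seed = 6))
  b <- make_random_subsets(u, cv_config(n_splits = 5, n_iterations = 2, seed = 6))
  expect_identical(a, b)
  c2 <- make_random_subsets(u, cv_config(n_splits = 5, n_iterations = 2, seed = 7))
  expect_false(identical(a, c2))
  # growing n_iterations does not change earlier iterations
  d <- make_random_subsets(u, cv_config(n_splits = 5, n_iterations = 4, seed = 6))
  expect_identical(d[1:2], a)
  expect_error(make_random_subsets(1:3, cv_config(n_splits = 5, seed = 1)),
               "at least n_splits")
})

test_that("select_components takes the smallest count at the minimum", {
  expect_identical(select_components(data.frame(
    n_components = 1:4, error = c(0.30, 0.20, 0.20, 0.25))), 2L)
  expect_identical(select_components(data.frame(
    n_components = 1:5, error = c(0.5, 0.4, 0.3, 0.2, 0.1))), 5L)
  expect_identical(select_components(data.frame(
    n_components = 3, error = 0.2)), 3L)
  expect_error(select_components(data.frame(n_components = integer(0),
                                            error = numeric(0))), "empty")
})

test_that("compute_metrics matches the confusion arithmetic", {
  pred <- c(rep(1, 19), 0, rep(0, 18), 1, 1)
  labels <- c(rep(1, 20), rep(0, 20))
  m <- compute_metrics(pred, labels, threshold = 0.5)
  expect_equal(m$sensitivity, 95)
  expect_equal(m$specificity, 90)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(19L, 1L, 18L, 2L))
  all_right <- compute_metrics(labels, labels, 0.5)
  expect_equal(all_right$sensitivity, 100)
  expect_equal(all_right$specificity, 100)
  expect_error(compute_metrics(pred[1:20], labels[1:20], 0.5), "both classes")
})

test_that("threshold sweep matches an exhaustive per-spectrum tally oracle", {
  set.seed(12)
  pred <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  for (thr in seq(-1, 1, length.out = 11)) {
    m <- compute_metrics(pred, labels, thr)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(pred)) {
      pos <- pred[i] >= thr
      if (labels[i] == 1 && pos) tp <- tp + 1
      if (labels[i] == 1 && !pos) fn <- fn + 1
      if (labels[i] == 0 && pos) fp <- fp + 1
      if (labels[i] == 0 && !pos) tn <- tn + 1
    }
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    expect_equal(m$sensitivity + 100 * fn / (tp + fn), 100)
    expect_equal(m$specificity + 100 * fp / (tn + fp), 100)
    expect_identical(m$tp + m$fp + m$tn + m$fn, length(pred))
  }
})

make_separable_dataset <- function(n = 60, seed = 3) {
  grid <- seq(400, 1800, by = 8)
  prof <- peak_profile(grid, 1004, 10, "lorentzian")
  base <- peak_profile(grid, 1450, 18, "gaussian") +
    peak_profile(grid, 1669, 30, "gaussian")
  labels <- rep(c(0, 1), n / 2)
  withr::with_seed(seed, {
    X <- t(vapply(labels, function(l) {
      base + (1 + 0.8 * l) * prof + rnorm(length(grid), sd = 0.002)
    }, numeric(length(grid))))
  })
  spectral_dataset(grid, X, tiny_meta(
    n, classes = ifelse(labels == 1, "HSIL", "negative"),
    patients = sprintf("p%02d", rep_len(1:10, n))))
}

test_that("noiseless separable data gives zero CV error and perfect metrics", {
  ds <- make_separable_dataset()
  cfg <- cv_config(n_splits = 10, n_iterations = 2, seed = 5)
  for (model in c("plsda", "pcalda")) {
    r <- cross_validate(ds, model, candidates = 1:3, cfg = cfg)
    expect_equal(min(r$curve$error), 0)
    expect_equal(r$metrics$sensitivity, 100)
    expect_equal(r$metrics$specificity, 100)
  }
})

test_that("every spectrum is predicted exactly once per iteration", {
  ds <- make_separable_dataset(n = 40)
  cfg <- cv_config(n_splits = 8, n_iterations = 3, seed = 9)
  r <- cross_validate(ds, "plsda", candidates = 1:2, cfg = cfg)
  expect_identical(length(r$predictions), 40L)
  expect_true(all(is.finite(r$predictions)))
})

test_that("patient grouping keeps all of a patient's spectra in one fold", {
  ds <- make_separable_dataset(n = 60)
  cfg <- cv_config(n_splits = 5, n_iterations = 4, grouping = "patient",
                   seed = 13)
  parts <- make_random_subsets(unique(ds$meta$patient_id), cfg)
  for (it in parts) {
    for (ts in it) {
      test_rows <- ds$meta$patient_id %in% ts
      expect_identical(
        intersect(unique(ds$meta$patient_id[test_rows]),
                  unique(ds$meta$patient_id[!test_rows])),
        character(0))
    }
  }
  r <- cross_validate(ds, "plsda", candidates = 1:2, cfg = cfg)
  expect_s3_class(r, "cv_report")
  expect_identical(r$grouping, "patient")
})

test_that("label permutation drives CV accuracy to chance", {
  grid <- seq(400, 1800, by = 16)
  n <- 60
  withr::with_seed(101, {
    X <- matrix(rnorm(n * length(grid), mean = 1, sd = 0.1), n)
  })
  accs <- vapply(1:3, function(k) {
    meta <- tiny_meta(n, classes = withr::with_seed(200 + k, {
      sample(rep(c("negative", "HSIL"), n / 2))
    }))
    ds <- spectral_dataset(grid, X, meta)
    r <- cross_validate(ds, "plsda", candidates = 1:3,
                        cfg = cv_config(n_splits = 6, n_iterations = 2,
                                        seed = 300 + k))
    y <- as.integer(ds$meta$cytology_class == "HSIL")
    mean((r$predictions >= 0.5) == y)
  }, numeric(1))
  # 99% binomial band around 0.5 for 3x60 pooled decisions
  half <- 2.576 * sqrt(0.25 / (3 * n))
  expect_lt(abs(mean(accs) - 0.5), half + 0.05)
})

test_that("cross_validate is deterministic and iteration-1 is seed-stable", {
  ds <- make_separable_dataset(n = 40)
  cfg1 <- cv_config(n_splits = 8, n_iterations = 1, seed = 17)
  cfg2 <- cv_config(n_splits = 8, n_iterations = 2, seed = 17)
  r1 <- cross_validate(ds, "plsda", candidates = 1:2, cfg = cfg1)
  r1b <- cross_validate(ds, "plsda", candidates = 1:2, cfg = cfg1)
  expect_identical(r1$predictions, r1b$predictions)
  expect_identical(r1$curve, r1b$curve)
  # with one iteration the averaged predictions are iteration 1's
  r2 <- cross_validate(ds, "plsda", candidates = 1:2, cfg = cfg2)
  expect_false(identical(r1$predictions, r2$predictions))  # averaging differs
  expect_identical(r2$config$n_iterations, 2L)
})
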