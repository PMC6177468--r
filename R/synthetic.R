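# Synthetic single-cell Raman spectra with the hierarchical structure the
# analysis assumes: cytology class -> patient -> cell -> spectrum. Band-level
# class effects act multiplicatively on peak amplitudes (Raman intensity
# scales with analyte concentration); a per-patient lognormal multiplier
# induces within-patient correlation; glass background, low-order polynomial
# baseline and i.i.d. Gaussian detector noise complete the forward model.

#' Evaluate a spectral line profile
#'
#' @param grid Wavenumber axis (cm^-1).
#' @param center Peak position (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return Numeric vector: unit-height profile on `grid`.
#' @export
peak_profile <- function(grid, center, fwhm,
                         shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be positive")
  d <- grid - center
  if (shape == "gaussian") {
    exp(-4 * log(2) * d^2 / fwhm^2)
  } else {
    1 / (1 + (2 * d / fwhm)^2)
  }
}

#' Default band table for cervical-cell spectra
#'
#' One row per Raman band used by the generator: position, full width at half
#' maximum, relative base height, lineshape and a tentative biochemical
#' assignment. Sharp rings (e.g. phenylalanine 1004 cm^-1) are Lorentzian,
#' broad bands (glycogen 482, amide I 1669 cm^-1) Gaussian.
#'
#' @return A `data.frame` with columns `center`, `fwhm`, `height`, `shape`,
#'   `assignment`.
#' @export
default_peak_table <- function() {
  tab <- rbind(
    c(482,  18, 0.55, "gaussian",   "glycogen"),
    c(621,  12, 0.25, "lorentzian", "C-C twist, phenylalanine"),
    c(644,  12, 0.22, "lorentzian", "C-C twist, tyrosine/phenylalanine"),
    c(728,  12, 0.20, "lorentzian", "adenine ring"),
    c(784,  14, 0.45, "lorentzian", "uracil/thymine/cytosine ring (DNA/RNA)"),
    c(828,  14, 0.30, "lorentzian", "PO2- stretch DNA, tyrosine"),
    c(855,  14, 0.40, "gaussian",   "ring breathing tyrosine/proline"),
    c(936,  16, 0.35, "gaussian",   "C-C stretch proline/valine, glycogen"),
    c(957,  14, 0.22, "gaussian",   "C-C/C-N, PO3 stretch (DNA)"),
    c(1004,  9, 0.70, "lorentzian", "phenylalanine ring breathing"),
    c(1092, 16, 0.35, "gaussian",   "symmetric PO2- stretch (DNA backbone)"),
    c(1127, 14, 0.28, "gaussian",   "C-N stretch, proteins"),
    c(1176, 12, 0.18, "lorentzian", "C-H bend trp/phe; cytosine, guanine"),
    c(1210, 14, 0.22, "lorentzian", "C-C6H5 stretch trp/phe"),
    c(1245, 22, 0.45, "gaussian",   "amide III"),
    c(1338, 20, 0.45, "gaussian",   "CH2/CH3 wag, collagen/nucleic acids"),
    c(1422, 16, 0.25, "gaussian",   "CH deformation, nucleic acids"),
    c(1450, 18, 0.80, "gaussian",   "CH2 bend, proteins/lipids"),
    c(1578, 14, 0.30, "lorentzian", "adenine/guanine (DNA/RNA)"),
    c(1610, 10, 0.22, "lorentzian", "C=C, tyrosine/phenylalanine"),
    c(1619, 10, 0.22, "lorentzian", "C=C, tryptophan"),
    c(1669, 30, 0.90, "gaussian",   "amide I")
  )
  data.frame(center = as.numeric(tab[, 1]), fwhm = as.numeric(tab[, 2]),
             height = as.numeric(tab[, 3]), shape = tab[, 4],
             assignment = tab[, 5], stringsAsFactors = FALSE)
}

#' Default HSIL class effects
#'
#' Multiplicative amplitude changes applied to HSIL spectra at the bands where
#' negative/HSIL differences are seeded: glycogen-related bands decrease,
#' nucleic-acid and protein bands increase. Magnitudes sit in the 30-45%
#' range; effect sizes are a calibration choice of the generator, not
#' measured quantities.
#'
#' @return A `data.frame` with columns `center`, `relative_change`.
#' @export
default_class_effects <- function() {
  data.frame(
    center = c(482, 621, 728, 828, 855, 936, 957, 1092,
               1176, 1210, 1422, 1450, 1578, 1610, 1619, 1669),
    relative_change = c(0.60, 1.30, 1.40, 1.30, 0.70, 0.70, 1.30, 1.35,
                        1.30, 1.30, 1.30, 1.30, 1.40, 1.35, 1.35, 1.30)
  )
}

#' Default superficial-vs-intermediate cell-type effects
#'
#' Weak (5-10%) multiplicative differences, mainly in glycogen content,
#' applied to superficial-cell spectra. Deliberately much smaller than the
#' class effects: inter-cell-type variability is the nuisance the mixed-cell
#' analysis must tolerate.
#'
#' @return A `data.frame` with columns `center`, `relative_change`.
#' @export
default_cell_type_effects <- function() {
  data.frame(center = c(482, 855, 936, 1004, 1669),
             relative_change = c(1.10, 1.05, 1.05, 0.95, 0.97))
}

#' Build the reference component library
#'
#' Returns a [basis_set()] with one smooth broad glass component (no feature
#' narrower than 200 cm^-1 FWHM) and six biochemical components (glycogen,
#' DNA, RNA, protein, collagen, lipid) assembled as sums of band profiles.
#'
#' @param grid Wavenumber axis covering 400-1800 cm^-1.
#' @return A `basis_set` with `background = TRUE` for the glass component.
#' @export
build_component_library <- function(grid) {
  grid <- as.numeric(grid)
  if (min(grid) > 400 || max(grid) < 1800) {
    stop("grid must cover 400-1800 cm^-1")
  }
  mix <- function(spec) {
    out <- numeric(length(grid))
    for (i in seq_len(nrow(spec))) {
      out <- out + spec[i, 3] * peak_profile(grid, spec[i, 1], spec[i, 2],
                                             if (spec[i, 4] == 1) "gaussian" else "lorentzian")
    }
    out
  }
  g <- 1; l <- 2
  glass <- 0.9 * peak_profile(grid, 560, 700, "gaussian") +
    0.7 * peak_profile(grid, 1100, 900, "gaussian") +
    0.35 * peak_profile(grid, 1450, 650, "gaussian")
  glycogen <- mix(rbind(
    c(482, 18, 1.00, g), c(855, 14, 0.45, g), c(936, 16, 0.55, g),
    c(1048, 18, 0.30, g), c(1338, 20, 0.25, g), c(1460, 18, 0.30, g)))
  dna <- mix(rbind(
    c(728, 12, 0.30, l), c(784, 14, 1.00, l), c(828, 14, 0.50, l),
    c(957, 14, 0.35, g), c(1092, 16, 0.80, g), c(1176, 12, 0.30, l),
    c(1422, 16, 0.40, g), c(1578, 14, 0.60, l), c(1669, 30, 0.20, g)))
  rna <- mix(rbind(
    c(784, 14, 0.80, l), c(811, 14, 0.50, l), c(1100, 18, 0.60, g),
    c(1240, 22, 0.40, g), c(1578, 14, 0.50, l)))
  protein <- mix(rbind(
    c(621, 12, 0.30, l), c(644, 12, 0.25, l), c(855, 14, 0.30, g),
    c(936, 16, 0.30, g), c(1004, 9, 1.00, l), c(1127, 14, 0.40, g),
    c(1210, 14, 0.30, l), c(1245, 22, 0.70, g), c(1338, 20, 0.60, g),
    c(1450, 18, 0.80, g), c(1610, 10, 0.25, l), c(1619, 10, 0.25, l),
    c(1669, 30, 1.00, g)))
  collagen <- mix(rbind(
    c(855, 14, 0.70, g), c(936, 16, 0.60, g), c(1245, 22, 1.00, g),
    c(1338, 20, 0.50, g), c(1450, 18, 0.60, g), c(1669, 30, 0.90, g)))
  lipid <- mix(rbind(
    c(1066, 14, 0.50, g), c(1301, 16, 0.80, g), c(1440, 16, 1.00, g),
    c(1669, 30, 0.30, g), c(1745, 18, 0.25, g)))
  comps <- cbind(glass = glass, glycogen = glycogen, dna = dna, rna = rna,
                 protein = protein, collagen = collagen, lipid = lipid)
  basis_set(grid, comps,
            background = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

# Evaluate a power-basis polynomial on the axis rescaled to [-1, 1]; keeps
# coefficient scales comparable across degrees.
eval_baseline_poly <- function(grid, coefs) {
  u <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  drop(outer(u, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Simulate one spectrum from a basis set
#'
#' Forward model: sum of biochemical components scaled by `amplitudes`, plus
#' `glass_coeff` times the background component(s), plus a polynomial baseline
#' evaluated on the axis rescaled to \[-1, 1\], plus i.i.d. Gaussian noise.
#'
#' @param basis A `basis_set`.
#' @param amplitudes Non-negative vector, one entry per non-background
#'   component (in column order).
#' @param baseline_coefs Polynomial coefficients (constant first); `NULL` or
#'   `0` for no baseline.
#' @param glass_coeff Non-negative scalar multiplying the background
#'   component(s).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param id Spectrum id.
#' @return A `raman_spectrum`. Uses the current RNG stream when
#'   `noise_sd > 0`.
#' @export
simulate_spectrum <- function(basis, amplitudes, baseline_coefs = NULL,
                              glass_coeff = 0, noise_sd = 0, id = "sim") {
  stopifnot(inherits(basis, "basis_set"))
  bio <- basis$components[, !basis$background, drop = FALSE]
  if (length(amplitudes) != ncol(bio)) {
    stop("need one amplitude per non-background component (",
         ncol(bio), "), got ", length(amplitudes))
  }
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (glass_coeff < 0) stop("glass_coeff must be non-negative")
  y <- drop(bio %*% amplitudes) +
    glass_coeff * rowSums(basis$components[, basis$background, drop = FALSE])
  if (!is.null(baseline_coefs) && any(baseline_coefs != 0)) {
    y <- y + eval_baseline_poly(basis$wavenumbers, baseline_coefs)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  raman_spectrum(basis$wavenumbers, y, id)
}

#' Configure a synthetic study
#'
#' Defaults reproduce the design of the emulated study: 18 negative and 17
#' HSIL patients, strata of 176/252 intermediate and 174/153 superficial
#' spectra (755 in total) on a 1 cm^-1 grid over 400-1800 cm^-1, with class
#' effects at the 16 reported difference bands.
#'
#' @param n_patients_per_class Named vector `c(negative=, HSIL=)`.
#' @param strata_counts Named totals
#'   `c(intermediate_negative=, intermediate_HSIL=, superficial_negative=,
#'   superficial_HSIL=)`; set `NULL` to instead draw `spectra_per_patient`
#'   cells per patient with type probability `cell_type_mix`.
#' @param spectra_per_patient Integer range `c(lo, hi)` (used when
#'   `strata_counts` is `NULL`).
#' @param cell_type_mix Probability a cell is intermediate (used when
#'   `strata_counts` is `NULL`).
#' @param peak_table Band table, see [default_peak_table()].
#' @param class_effects HSIL multiplicative effects, see
#'   [default_class_effects()]; centers must match `peak_table$center`.
#' @param cell_type_effects Superficial-cell multiplicative effects.
#' @param patient_sd SD (log scale) of per-patient lognormal amplitude
#'   multipliers shared by all of a patient's spectra.
#' @param noise_sd Additive Gaussian noise SD per grid point.
#' @param glass_coeff_range Uniform range for the per-spectrum glass
#'   coefficient.
#' @param baseline_poly_degree Degree of the random polynomial baseline.
#' @param baseline_coeff_sd SD of its coefficients (axis rescaled to
#'   \[-1, 1\]).
#' @param grid Wavenumber axis.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients_per_class = c(negative = 18, HSIL = 17),
                             strata_counts = c(intermediate_negative = 176,
                                               intermediate_HSIL = 252,
                                               superficial_negative = 174,
                                               superficial_HSIL = 153),
                             spectra_per_patient = c(10, 15),
                             cell_type_mix = 0.5,
                             peak_table = default_peak_table(),
                             class_effects = default_class_effects(),
                             cell_type_effects = default_cell_type_effects(),
                             patient_sd = 0.10,
                             noise_sd = 0.01,
                             glass_coeff_range = c(0.8, 1.2),
                             baseline_poly_degree = 3,
                             baseline_coeff_sd = 0.01,
                             grid = seq(400, 1800, by = 1),
                             seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(all(n_patients_per_class >= 1),
            cell_type_mix >= 0, cell_type_mix <= 1,
            spectra_per_patient[1] >= 1,
            spectra_per_patient[1] <= spectra_per_patient[2],
            patient_sd >= 0, noise_sd >= 0,
            glass_coeff_range[1] >= 0,
            glass_coeff_range[1] <= glass_coeff_range[2],
            baseline_poly_degree >= 0, baseline_coeff_sd >= 0)
  if (!all(c("negative", "HSIL") %in% names(n_patients_per_class))) {
    stop("n_patients_per_class needs 'negative' and 'HSIL' entries")
  }
  stopifnot(all(peak_table$fwhm > 0), all(peak_table$height >= 0),
            all(peak_table$center >= 400 & peak_table$center <= 1800))
  check_effects <- function(eff, what) {
    if (is.null(eff) || nrow(eff) == 0) return(invisible())
    if (any(eff$relative_change <= 0)) stop(what, ": relative_change must be > 0")
    missing <- setdiff(eff$center, peak_table$center)
    if (length(missing)) {
      stop(what, ": effect center(s) ", paste(missing, collapse = ", "),
           " not present in peak_table")
    }
  }
  check_effects(class_effects, "class_effects")
  check_effects(cell_type_effects, "cell_type_effects")
  if (!is.null(strata_counts)) {
    need <- c("intermediate_negative", "intermediate_HSIL",
              "superficial_negative", "superficial_HSIL")
    if (!all(need %in% names(strata_counts))) {
      stop("strata_counts needs entries ", paste(need, collapse = ", "))
    }
    stopifnot(all(strata_counts >= 1))
  }
  structure(list(
    n_patients_per_class = n_patients_per_class,
    strata_counts = strata_counts,
    spectra_per_patient = as.integer(spectra_per_patient),
    cell_type_mix = cell_type_mix,
    peak_table = peak_table, class_effects = class_effects,
    cell_type_effects = cell_type_effects,
    patient_sd = patient_sd, noise_sd = noise_sd,
    glass_coeff_range = glass_coeff_range,
    baseline_poly_degree = as.integer(baseline_poly_degree),
    baseline_coeff_sd = baseline_coeff_sd,
    grid = as.numeric(grid), seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Read a synthetic-study configuration from YAML
#'
#' Recognised keys mirror the arguments of [synthetic_config()]; `peak_table`,
#' `class_effects` and `cell_type_effects` may be given as lists of records.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind.data.frame, c(x, list(stringsAsFactors = FALSE)))
  args <- raw
  for (k in c("peak_table", "class_effects", "cell_type_effects")) {
    if (!is.null(raw[[k]])) args[[k]] <- to_df(raw[[k]])
  }
  for (k in c("n_patients_per_class", "strata_counts")) {
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$grid) && length(raw$grid) == 3 && is.list(raw$grid)) {
    args$grid <- seq(raw$grid$from, raw$grid$to, by = raw$grid$by)
  }
  do.call(synthetic_config, args)
}

# Distribute `total` measurements over `k` patients as evenly as possible,
# remainder assigned to randomly chosen patients.
allocate_counts <- function(total, k) {
  counts <- rep(total %/% k, k)
  rem <- total - sum(counts)
  if (rem > 0) {
    bump <- sample.int(k, rem)
    counts[bump] <- counts[bump] + 1L
  }
  counts
}

#' Simulate a full labelled study
#'
#' Draws patients per class, a lognormal per-patient amplitude multiplier per
#' band, per-spectrum glass coefficient, polynomial baseline and noise; HSIL
#' spectra apply the class effects and superficial cells the cell-type effects
#' multiplicatively to the matched band amplitudes. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `dataset` (a `spectral_dataset`), `truth` (per-spectrum
#'   latent band amplitudes, glass and baseline coefficients, the peak-level
#'   basis, and the effect tables applied) and `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    grid <- cfg$grid
    pt <- cfg$peak_table
    np <- nrow(pt)
    profiles <- vapply(seq_len(np), function(i) {
      peak_profile(grid, pt$center[i], pt$fwhm[i], pt$shape[i])
    }, numeric(length(grid)))  # n_points x n_peaks
    glass <- 0.9 * peak_profile(grid, 560, 700, "gaussian") +
      0.7 * peak_profile(grid, 1100, 900, "gaussian") +
      0.35 * peak_profile(grid, 1450, 650, "gaussian")
    glass_scale <- 2.0  # raw spectra are glass-dominated

    effect_vec <- function(eff) {
      v <- rep(1, np)
      if (!is.null(eff) && nrow(eff)) {
        v[match(eff$center, pt$center)] <- eff$relative_change
      }
      v
    }
    class_mult <- effect_vec(cfg$class_effects)      # applied to HSIL
    type_mult <- effect_vec(cfg$cell_type_effects)   # applied to superficial

    patients <- list(
      negative = sprintf("N%02d", seq_len(cfg$n_patients_per_class[["negative"]])),
      HSIL = sprintf("H%02d", seq_len(cfg$n_patients_per_class[["HSIL"]]))
    )

    # per-spectrum design rows: patient, class, cell type
    design <- NULL
    if (!is.null(cfg$strata_counts)) {
      for (cls in c("negative", "HSIL")) {
        ids <- patients[[cls]]
        for (ct in c("intermediate", "superficial")) {
          total <- cfg$strata_counts[[paste0(ct, "_", cls)]]
          counts <- allocate_counts(total, length(ids))
          design <- rbind(design, data.frame(
            patient_id = rep(ids, counts), cytology_class = cls,
            cell_type = ct, stringsAsFactors = FALSE))
        }
      }
    } else {
      for (cls in c("negative", "HSIL")) {
        for (pid in patients[[cls]]) {
          ncell <- sample(seq(cfg$spectra_per_patient[1],
                              cfg$spectra_per_patient[2]), 1)
          ct <- ifelse(stats::runif(ncell) < cfg$cell_type_mix,
                       "intermediate", "superficial")
          design <- rbind(design, data.frame(
            patient_id = pid, cytology_class = cls, cell_type = ct,
            stringsAsFactors = FALSE))
        }
      }
    }
    n <- nrow(design)

    # lognormal per-patient multiplier, one per band, shared across spectra
    all_pat <- unlist(patients, use.names = FALSE)
    pat_mult <- matrix(exp(stats::rnorm(length(all_pat) * np, 0, cfg$patient_sd)),
                       nrow = length(all_pat), dimnames = list(all_pat, NULL))

    amps <- matrix(0, n, np)
    for (i in seq_len(n)) {
      a <- pt$height * pat_mult[design$patient_id[i], ]
      if (design$cytology_class[i] == "HSIL") a <- a * class_mult
      if (design$cell_type[i] == "superficial") a <- a * type_mult
      amps[i, ] <- a
    }
    glass_coeffs <- stats::runif(n, cfg$glass_coeff_range[1],
                                 cfg$glass_coeff_range[2])
    nb <- cfg$baseline_poly_degree + 1L
    base_coefs <- matrix(stats::rnorm(n * nb, 0, cfg$baseline_coeff_sd), n, nb)

    clean <- amps %*% t(profiles) +
      outer(glass_coeffs * glass_scale, glass) +
      t(apply(base_coefs, 1, function(b) eval_baseline_poly(grid, b)))
    noise <- if (cfg$noise_sd > 0) {
      matrix(stats::rnorm(n * length(grid), 0, cfg$noise_sd), n)
    } else 0
    mat <- clean + noise

    sid <- sprintf("%s_%s_c%03d", design$patient_id,
                   substr(design$cell_type, 1, 3), seq_len(n))
    meta <- cell_meta(sid, design$patient_id, design$cytology_class,
                      design$cell_type)
    comp <- cbind(glass = glass * glass_scale, profiles)
    colnames(comp) <- c("glass", sprintf("band_%g", pt$center))
    basis <- basis_set(grid, pmax(comp, 0),
                       background = c(TRUE, rep(FALSE, np)))
    truth <- list(
      peak_table = pt,
      amplitudes = `dimnames<-`(amps, list(sid, sprintf("band_%g", pt$center))),
      glass_coeffs = stats::setNames(glass_coeffs, sid),
      baseline_coefs = `rownames<-`(base_coefs, sid),
      class_multipliers = class_mult, cell_type_multipliers = type_mult,
      patient_multipliers = pat_mult, basis = basis
    )
    list(dataset = spectral_dataset(grid, mat, meta), truth = truth,
         config = cfg)
  })
}

#' Reconstruct the noise-free signal from a study's ground truth
#'
#' @param truth The `truth` element returned by [simulate_study()].
#' @return Matrix of noise-free intensities (one row per spectrum): band
#'   amplitudes times profiles, plus glass and baseline. Equals the generated
#'   matrix exactly when `noise_sd = 0`.
#' @export
reconstruct_truth <- function(truth) {
  basis <- truth$basis
  profiles <- basis$components[, !basis$background, drop = FALSE]
  glass <- rowSums(basis$components[, basis$background, drop = FALSE])
  truth$amplitudes %*% t(profiles) +
    outer(truth$glass_coeffs, glass) +
    t(apply(truth$baseline_coefs, 1,
            function(b) eval_baseline_poly(basis$wavenumbers, b)))
}
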