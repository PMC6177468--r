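#' @keywords internal
"_PACKAGE"

CYTOLOGY_CLASSES <- c("negative", "HSIL")
CELL_TYPES <- c("intermediate", "superficial")

#' Construct a single Raman spectrum
#'
#' A spectrum is a strictly increasing wavenumber axis (cm^-1) with one
#' intensity value per grid point and an opaque identifier.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing.
#' @param intensities Numeric vector of detector counts, same length as
#'   `wavenumbers`, all finite.
#' @param id Character scalar identifying the measurement.
#' @return An object of class `raman_spectrum` (list with `wavenumbers`,
#'   `intensities`, `id`).
#' @export
raman_spectrum <- function(wavenumbers, intensities, id = "spectrum") {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) == 0L) stop("spectrum must contain at least one point")
  if (any(!is.finite(wavenumbers))) stop("wavenumbers must be finite")
  if (any(diff(wavenumbers) <= 0)) stop("wavenumbers must be strictly increasing")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         id = as.character(id)[1]),
    class = "raman_spectrum"
  )
}

#' Validate and construct per-cell metadata
#'
#' @param spectrum_id Character vector of unique spectrum identifiers.
#' @param patient_id Character vector of patient identifiers.
#' @param cytology_class Character vector, each `"negative"` or `"HSIL"`.
#' @param cell_type Character vector, each `"intermediate"` or `"superficial"`.
#' @return A `data.frame` with the four validated columns.
#' @export
cell_meta <- function(spectrum_id, patient_id, cytology_class, cell_type) {
  spectrum_id <- as.character(spectrum_id)
  patient_id <- as.character(patient_id)
  cytology_class <- as.character(cytology_class)
  cell_type <- as.character(cell_type)
  n <- length(spectrum_id)
  if (length(patient_id) != n || length(cytology_class) != n ||
      length(cell_type) != n) {
    stop("all metadata columns must have equal length")
  }
  if (anyDuplicated(spectrum_id)) stop("spectrum_id values must be unique")
  bad <- setdiff(unique(cytology_class), CYTOLOGY_CLASSES)
  if (length(bad)) {
    stop("unknown cytology_class value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CYTOLOGY_CLASSES, collapse = ", "), ")")
  }
  bad <- setdiff(unique(cell_type), CELL_TYPES)
  if (length(bad)) {
    stop("unknown cell_type value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CELL_TYPES, collapse = ", "), ")")
  }
  data.frame(spectrum_id = spectrum_id, patient_id = patient_id,
             cytology_class = cytology_class, cell_type = cell_type,
             stringsAsFactors = FALSE)
}

#' Construct a labelled spectral dataset
#'
#' All spectra in a dataset share one wavenumber axis; intensities are held as
#' an `n_spectra x n_points` matrix with one metadata row per spectrum.
#'
#' @param wavenumbers Shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, one row per spectrum, `length(wavenumbers)`
#'   columns, all entries finite.
#' @param meta Metadata `data.frame` as returned by [cell_meta()], one row per
#'   spectrum.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumbers, intensities, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be finite and strictly increasing")
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensity matrix must have one column per wavenumber")
  }
  if (nrow(intensities) > 0 && any(!is.finite(intensities))) {
    stop("intensities must be finite")
  }
  meta <- cell_meta(meta$spectrum_id, meta$patient_id,
                    meta$cytology_class, meta$cell_type)
  if (nrow(meta) != nrow(intensities)) {
    stop("meta must have one row per spectrum (",
         nrow(meta), " vs ", nrow(intensities), ")")
  }
  rownames(intensities) <- meta$spectrum_id
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities, meta = meta),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points (%g-%g cm^-1)\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (nrow(x$meta)) {
    print(table(class = x$meta$cytology_class, cell = x$meta$cell_type))
  }
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds A `spectral_dataset`.
#' @return Integer count of rows.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Subset a dataset by row
#' @param ds A `spectral_dataset`.
#' @param idx Row indices or logical mask.
#' @return A `spectral_dataset` with the selected spectra.
#' @export
subset_dataset <- function(ds, idx) {
  spectral_dataset(ds$wavenumbers, ds$intensities[idx, , drop = FALSE],
                   ds$meta[idx, , drop = FALSE])
}

#' Construct a basis set of reference spectra
#'
#' A basis set holds named reference spectra on a shared axis: at least one
#' background component (glass slide) plus biochemical components used to
#' stabilise the non-negative background fit.
#'
#' @param wavenumbers Shared axis (cm^-1), strictly increasing.
#' @param components Numeric matrix, one column per component (named), all
#'   values non-negative.
#' @param background Logical vector, one flag per component; `TRUE` marks a
#'   background (glass) component that gets subtracted.
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(wavenumbers, components, background) {
  wavenumbers <- as.numeric(wavenumbers)
  if (any(diff(wavenumbers) <= 0)) stop("wavenumbers must be strictly increasing")
  components <- as.matrix(components)
  if (nrow(components) != length(wavenumbers)) {
    stop("components must have one row per wavenumber")
  }
  if (is.null(colnames(components))) {
    stop("components must be named (column names)")
  }
  if (any(!is.finite(components)) || any(components < 0)) {
    stop("basis components must be finite and non-negative")
  }
  background <- as.logical(background)
  if (length(background) != ncol(components)) {
    stop("one background flag per component required")
  }
  if (!any(background)) stop("at least one background component required")
  structure(
    list(wavenumbers = wavenumbers, components = components,
         background = background),
    class = "basis_set"
  )
}

#' Crop a dataset to a wavenumber window
#'
#' Retains exactly the grid points with `lo <= w <= hi` (closed interval);
#' typically used to restrict to the 400-1800 cm^-1 fingerprint region.
#'
#' @param ds A `spectral_dataset`.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return The cropped `spectral_dataset`.
#' @export
crop_fingerprint <- function(ds, lo = 400, hi = 1800) {
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- ds$wavenumbers >= lo & ds$wavenumbers <= hi
  if (!any(keep)) stop("crop window [", lo, ", ", hi, "] does not overlap the axis")
  spectral_dataset(ds$wavenumbers[keep],
                   ds$intensities[, keep, drop = FALSE], ds$meta)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation within the measured span; extrapolation is refused so
#' no intensity is invented outside the measurement.
#'
#' @param s A `raman_spectrum`.
#' @param grid Target wavenumber axis, strictly increasing, inside
#'   `range(s$wavenumbers)`.
#' @return A `raman_spectrum` on `grid`.
#' @export
align_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "raman_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  rng <- range(s$wavenumbers)
  if (min(grid) < rng[1] || max(grid) > rng[2]) {
    stop("grid extends beyond the measured span [", rng[1], ", ", rng[2],
         "]; extrapolation is not supported")
  }
  y <- stats::approx(s$wavenumbers, s$intensities, xout = grid,
                     method = "linear", ties = "ordered")$y
  raman_spectrum(grid, y, s$id)
}
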