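# Wide-CSV dialect: column 1 `wavenumber_cm1`, one column per spectrum id;
# metadata sidecar `<stem>.meta.csv` with columns spectrum_id, patient_id,
# cytology_class, cell_type. Numbers are written with 17 significant digits so
# write/read round-trips are bit-exact.

meta_sidecar_path <- function(path) sub("\\.csv$", ".meta.csv", path)

#' Read a labelled spectral dataset
#'
#' Two on-disk layouts are supported. `wide_csv`: a single CSV whose first
#' column is `wavenumber_cm1` and whose remaining columns are one spectrum
#' each, plus a metadata sidecar `<stem>.meta.csv`. `jcamp_dir`: a directory
#' of single-spectrum JCAMP-DX files (plain AFFN `##XYDATA=(X++(Y..Y))`
#' records) plus a `meta.csv` in the same directory; all files must share one
#' wavenumber axis.
#'
#' @param path CSV file path (`wide_csv`) or directory (`jcamp_dir`).
#' @param format `"wide_csv"` (default) or `"jcamp_dir"`.
#' @return A `spectral_dataset`.
#' @export
read_dataset <- function(path, format = c("wide_csv", "jcamp_dir")) {
  format <- match.arg(format)
  if (format == "wide_csv") read_wide_csv(path) else read_jcamp_dir(path)
}

read_meta_csv <- function(path, ids) {
  if (!file.exists(path)) stop("metadata sidecar not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("spectrum_id", "patient_id", "cytology_class", "cell_type")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("metadata file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_rows <- setdiff(ids, m$spectrum_id)
  if (length(missing_rows)) {
    stop("metadata row missing for spectrum column(s): ",
         paste(missing_rows, collapse = ", "))
  }
  m <- m[match(ids, m$spectrum_id), , drop = FALSE]
  cell_meta(m$spectrum_id, m$patient_id, m$cytology_class, m$cell_type)
}

read_wide_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "wavenumber_cm1") {
    stop("first column must be named 'wavenumber_cm1', got '", names(d)[1], "'")
  }
  w <- as.numeric(d[[1]])
  if (nrow(d) > 0 && any(diff(w) <= 0)) {
    stop("wavenumber axis in ", path, " is not strictly increasing")
  }
  ids <- names(d)[-1]
  if (length(ids) < 1) stop("wide CSV must contain at least one spectrum column")
  meta <- read_meta_csv(meta_sidecar_path(path), ids)
  mat <- t(as.matrix(d[, -1, drop = FALSE]))
  spectral_dataset(w, mat, meta)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a spectral dataset as wide CSV plus metadata sidecar
#'
#' Inverse of [read_dataset()] for the `wide_csv` layout; numeric values keep
#' full double precision so the round-trip is bit-exact.
#'
#' @param ds A `spectral_dataset`.
#' @param path Output CSV path; metadata goes to `<stem>.meta.csv`.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  cols <- c(list(wavenumber_cm1 = fmt17(ds$wavenumbers)),
            stats::setNames(
              lapply(seq_len(n_spectra(ds)),
                     function(i) fmt17(ds$intensities[i, ])),
              ds$meta$spectrum_id))
  df <- if (n_spectra(ds) == 0 && length(ds$wavenumbers) == 0) {
    stats::setNames(data.frame(character(0)), "wavenumber_cm1")
  } else {
    as.data.frame(cols, check.names = FALSE, optional = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(ds$meta, meta_sidecar_path(path), row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read one spectrum from a JCAMP-DX file
#'
#' Supports the plain-number (AFFN) `##XYDATA=(X++(Y..Y))` dialect: each data
#' line is an abscissa followed by one or more ordinates, scaled by
#' `##XFACTOR`/`##YFACTOR` when present. Compressed (SQZ/DIF/DUP) forms are
#' not supported.
#'
#' @param path Path to a `.jdx`/`.dx` file containing a single spectrum.
#' @param id Spectrum id; defaults to the file stem.
#' @return A `raman_spectrum`.
#' @export
read_jcamp <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA record in ", path)
  form <- toupper(gsub("\\s", "", sub("^##XYDATA\\s*=", "",
                                      lines[start[1]], ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    stop("unsupported XYDATA form '", form, "' in ", path)
  }
  body <- lines[(start[1] + 1):length(lines)]
  end <- grep("^##", body)
  if (length(end)) body <- body[seq_len(end[1] - 1)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  if (any(grepl("[A-DF-Za-df-z%@]", body))) {
    stop("compressed JCAMP data forms are not supported (", path, ")")
  }
  w <- numeric(0); y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(ln, "[\\s,;]+", perl = TRUE)[[1]])
    if (length(vals) < 2 || any(is.na(vals))) {
      stop("malformed JCAMP data line: '", ln, "'")
    }
    w <- c(w, vals[1] * xfac)
    y <- c(y, vals[-1] * yfac)
  }
  npt <- as.numeric(get_field("NPOINTS"))
  if (length(npt) && !is.na(npt) && npt != length(y)) {
    stop("##NPOINTS=", npt, " but ", length(y), " ordinates read from ", path)
  }
  # the recorded X values anchor line starts; intermediate points are evenly
  # spaced within each line
  grid <- jcamp_expand_axis(w, y, body, xfac,
                            as.numeric(get_field("LASTX")))
  raman_spectrum(grid, y, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jcamp_expand_axis <- function(line_x, y, body, xfac, lastx) {
  if (!length(lastx)) lastx <- NA_real_
  counts <- vapply(body, function(ln) {
    length(strsplit(trimws(ln), "[\\s,;]+", perl = TRUE)[[1]]) - 1L
  }, integer(1))
  n <- sum(counts)
  ends <- c(line_x[-1], if (is.na(lastx)) NA_real_ else lastx)
  grid <- numeric(0)
  for (i in seq_along(line_x)) {
    k <- counts[i]
    if (k == 1L) { grid <- c(grid, line_x[i]); next }
    stop_x <- ends[i]
    if (is.na(stop_x)) {
      step <- if (i > 1) (line_x[i] - line_x[i - 1]) / counts[i - 1] else 1
      grid <- c(grid, line_x[i] + step * (seq_len(k) - 1))
    } else {
      denom <- if (i == length(line_x)) k - 1L else k
      grid <- c(grid, line_x[i] + (stop_x - line_x[i]) * (seq_len(k) - 1) /
                  max(denom, 1L))
    }
  }
  stopifnot(length(grid) == n)
  grid
}

read_jcamp_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.(jdx|dx)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no JCAMP-DX files in ", path)
  specs <- lapply(files, read_jcamp)
  axis <- specs[[1]]$wavenumbers
  for (s in specs) {
    if (length(s$wavenumbers) != length(axis) ||
        any(abs(s$wavenumbers - axis) > 1e-9)) {
      stop("JCAMP files do not share one wavenumber axis; resample with ",
           "align_to_grid() first (offending spectrum: ", s$id, ")")
    }
  }
  mat <- do.call(rbind, lapply(specs, function(s) s$intensities))
  ids <- vapply(specs, function(s) s$id, character(1))
  meta <- read_meta_csv(file.path(path, "meta.csv"), ids)
  spectral_dataset(axis, mat, meta)
}
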