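#' Construct a UV-visible absorbance spectrum
#'
#' A spectrum is a tibble with two numeric columns, `wavelength_nm` (strictly
#' increasing) and `absorbance` (absorbance units; negative baseline noise is
#' allowed and deliberately not clipped), carrying free-form metadata such as
#' sample name, pH, Al equivalents and cuvette path length.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, at least 2 values.
#' @param absorbance Numeric vector of absorbances (AU), same length.
#' @param metadata Named list of free-form metadata.
#' @return A tibble of class `"spectrum"` with columns `wavelength_nm` and
#'   `absorbance`; metadata is stored in the `"metadata"` attribute.
#' @examples
#' s <- spectrum(400:700, exp(-((400:700) - 640)^2 / (2 * 35^2)))
#' find_lambda_max(s)
#' @export
spectrum <- function(wavelength_nm, absorbance, metadata = list()) {
  x <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    absorbance = as.numeric(absorbance)
  )
  x <- structure(x, class = c("spectrum", class(tibble::tibble())),
                 metadata = metadata)
  validate_spectrum(x)
}

#' @rdname spectrum
#' @param x Object to validate.
#' @export
validate_spectrum <- function(x) {
  if (!all(c("wavelength_nm", "absorbance") %in% names(x))) {
    rlang::abort("a spectrum needs columns `wavelength_nm` and `absorbance`")
  }
  w <- x$wavelength_nm
  if (length(w) < 2) rlang::abort("a spectrum needs at least 2 points")
  if (anyNA(w) || anyNA(x$absorbance)) {
    rlang::abort("spectrum contains missing values")
  }
  if (any(diff(w) == 0)) {
    rlang::abort(sprintf("duplicate wavelengths: %s nm",
                         paste(unique(w[duplicated(w)]), collapse = ", ")))
  }
  if (any(diff(w) < 0)) rlang::abort("wavelengths must be strictly increasing")
  res <- stats::median(diff(w))
  if (!is.finite(res) || res <= 0) rlang::abort("spectral resolution must be finite and positive")
  x
}

#' Metadata of a spectrum, chromatogram or other series object
#' @param x Object carrying a `"metadata"` attribute.
#' @return A named list (possibly empty).
#' @export
series_metadata <- function(x) attr(x, "metadata") %||% list()

#' Median wavelength spacing of a spectrum
#' @param s A [spectrum()].
#' @return Median grid spacing in nm.
#' @export
spectral_resolution <- function(s) stats::median(diff(s$wavelength_nm))

is_uniform_grid <- function(w, tol = 1e-8) {
  d <- diff(w)
  max(d) - min(d) <= tol * max(abs(d))
}

#' Read a two-column spectrum CSV
#'
#' Expects two numeric columns (wavelength in nm, absorbance in AU) with an
#' optional single header line, UTF-8 encoded, "." as decimal separator.
#' Rows are sorted by wavelength on read.
#'
#' @param path File path.
#' @param sep Field separator (default ",").
#' @param metadata Metadata list attached to the result.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sep = ",", metadata = list()) {
  df <- read_two_column(path, sep, c("wavelength_nm", "absorbance"))
  df <- dplyr::arrange(df, .data$wavelength_nm)
  spectrum(df$wavelength_nm, df$absorbance,
           metadata = c(metadata, list(source = path)))
}

# shared two-numeric-column reader with line-accurate parse errors
read_two_column <- function(path, sep, col_names) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort(sprintf("empty file: %s", path))
  parse_line <- function(l) suppressWarnings(as.numeric(strsplit(l, sep, fixed = TRUE)[[1]]))
  first <- parse_line(lines[[1]])
  has_header <- anyNA(first) || length(first) < 2
  data_lines <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  vals <- lapply(data_lines, parse_line)
  bad <- which(vapply(vals, function(v) length(v) != 2 || anyNA(v), logical(1)))
  if (length(bad) > 0) {
    rlang::abort(sprintf("non-numeric or malformed row at line %d of %s",
                         bad[[1]] + offset, path))
  }
  m <- do.call(rbind, vals)
  tibble::tibble(!!col_names[1] := m[, 1], !!col_names[2] := m[, 2])
}

#' Write a spectrum CSV (6 significant digits)
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  s <- validate_spectrum(s)
  lines <- c("wavelength_nm,absorbance",
             sprintf("%.6g,%.6g", s$wavelength_nm, s$absorbance))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation between measured points; extrapolation outside the
#' measured support is refused. Grid points that coincide with original
#' wavelengths reproduce the original absorbances exactly.
#'
#' @param s A [spectrum()].
#' @param grid Strictly increasing wavelength vector within the support of `s`.
#' @return A [spectrum()] on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  s <- validate_spectrum(s)
  grid <- as.numeric(grid)
  lo <- min(s$wavelength_nm); hi <- max(s$wavelength_nm)
  if (min(grid) < lo || max(grid) > hi) {
    rlang::abort(sprintf(
      "resampling grid [%g, %g] nm extends beyond measured support [%g, %g] nm",
      min(grid), max(grid), lo, hi))
  }
  a <- stats::approx(s$wavelength_nm, s$absorbance, xout = grid,
                     method = "linear", ties = "ordered")$y
  if (length(grid) < 2) {
    # degenerate single-point query: a bare tibble, not a full spectrum
    return(tibble::tibble(wavelength_nm = grid, absorbance = a))
  }
  spectrum(grid, a, metadata = series_metadata(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
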