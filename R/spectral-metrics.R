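#' Wavelength of maximum absorbance within an analysis window
#'
#' Finds the global absorbance maximum of the sampled spectrum restricted to
#' `window` (default 400-700 nm, the visible range). On a plateau or exact
#' tie the longer wavelength wins, so output is deterministic.
#'
#' @param s A [spectrum()].
#' @param window Numeric length-2, analysis window in nm.
#' @return One-row tibble with `lambda_max_nm`, `a_max`, `window_low_nm`,
#'   `window_high_nm`.
#' @examples
#' s <- spectrum(400:700, exp(-((400:700) - 640)^2 / (2 * 35^2)))
#' find_lambda_max(s)$lambda_max_nm
#' @export
find_lambda_max <- function(s, window = c(400, 700)) {
  s <- validate_spectrum(s)
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- s$wavelength_nm >= window[1] & s$wavelength_nm <= window[2]
  if (!any(keep)) {
    rlang::abort(sprintf(
      "analysis window [%g, %g] nm does not overlap the spectrum support [%g, %g] nm",
      window[1], window[2], min(s$wavelength_nm), max(s$wavelength_nm)))
  }
  w <- s$wavelength_nm[keep]; a <- s$absorbance[keep]
  amax <- max(a)
  # tie-break toward the longer wavelength
  i <- max(which(a == amax))
  tibble::tibble(lambda_max_nm = w[i], a_max = amax,
                 window_low_nm = window[1], window_high_nm = window[2])
}

#' Violet contribution: left-Riemann area of absorbance over 500-600 nm
#'
#' The violet contribution (VC) of a blue colorant is the area under its
#' absorbance curve between 500 and 600 nm, computed as a left Riemann sum:
#' absorbance at each left endpoint times the grid spacing. 600 nm itself is
#' excluded as the final right endpoint. Low VC indicates a purer cyan.
#' Non-uniform grids are first resampled to 1 nm spacing; signed absorbances
#' are summed without clipping so baseline noise is not silently biased.
#'
#' @param s A [spectrum()] whose support covers the window.
#' @param vc_window Numeric length-2 integration window in nm (default 500-600).
#' @return Area in nm*AU (scalar).
#' @examples
#' flat <- spectrum(480:620, rep(1, 141))
#' violet_contribution(flat) # 100
#' @export
violet_contribution <- function(s, vc_window = c(500, 600)) {
  s <- validate_spectrum(s)
  stopifnot(length(vc_window) == 2, vc_window[1] < vc_window[2])
  lo <- min(s$wavelength_nm); hi <- max(s$wavelength_nm)
  if (lo > vc_window[1] || hi < vc_window[2]) {
    missing_lo <- if (lo > vc_window[1]) sprintf("[%g, %g]", vc_window[1], min(lo, vc_window[2])) else NULL
    missing_hi <- if (hi < vc_window[2]) sprintf("[%g, %g]", max(hi, vc_window[1]), vc_window[2]) else NULL
    rlang::abort(sprintf("spectrum does not cover the VC window: missing %s nm",
                         paste(c(missing_lo, missing_hi), collapse = " and ")))
  }
  if (!is_uniform_grid(s$wavelength_nm)) {
    s <- resample_spectrum(s, seq(vc_window[1], vc_window[2], by = 1))
  }
  step <- diff(s$wavelength_nm)[1]
  left <- s$wavelength_nm >= vc_window[1] & s$wavelength_nm < vc_window[2]
  sum(s$absorbance[left]) * step
}

#' Bathochromic (red) shift between two spectra
#'
#' Difference lambda_max(shifted) - lambda_max(reference) over a common
#' analysis window; positive values are red-shifts. Metal complexation of
#' anthocyanins (e.g. one-third equivalent Al3+ added to P2 at pH 7) shows up
#' as a large positive shift.
#'
#' @param reference,shifted [spectrum()] objects.
#' @param window Analysis window passed to [find_lambda_max()].
#' @return Shift in nm (scalar).
#' @export
bathochromic_shift <- function(reference, shifted, window = c(400, 700)) {
  find_lambda_max(shifted, window)$lambda_max_nm -
    find_lambda_max(reference, window)$lambda_max_nm
}

#' Summary spectral metrics for one spectrum
#'
#' @inheritParams find_lambda_max
#' @param vc_window Violet-contribution window.
#' @return One-row tibble: `lambda_max_nm`, `a_max`, `violet_contribution`.
#' @export
spectral_metrics <- function(s, window = c(400, 700), vc_window = c(500, 600)) {
  lm <- find_lambda_max(s, window)
  tibble::tibble(lambda_max_nm = lm$lambda_max_nm, a_max = lm$a_max,
                 violet_contribution = violet_contribution(s, vc_window))
}
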