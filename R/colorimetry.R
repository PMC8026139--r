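#' Colorimetry settings
#'
#' The study's instrument geometry is not specified, so observer and
#' illuminant are explicit configuration with conventional defaults:
#' CIE 1931 2-degree observer under illuminant D65 at 1-nm steps.
#'
#' @param observer Standard observer identifier.
#' @param illuminant Illuminant identifier (`"D65"` or `"E"`).
#' @param step_nm Integration step in nm.
#' @param path_scale Dimensionless path-length scaling applied to absorbance
#'   (e.g. 0.1 to predict a 1-mm cell from 10-mm data).
#' @return A list of class `"colorimetry_settings"`.
#' @export
colorimetry_settings <- function(observer = "cie1931_2deg", illuminant = "D65",
                                 step_nm = 1, path_scale = 1) {
  stopifnot(step_nm > 0, path_scale > 0)
  structure(list(observer = observer, illuminant = illuminant,
                 step_nm = step_nm, path_scale = path_scale),
            class = "colorimetry_settings")
}

#' Convert absorbance to transmittance (Beer-Lambert)
#'
#' T(lambda) = 10^(-A(lambda) * path_scale), clipped to the physical
#' range \[0, 1\].
#'
#' @param s An absorbance [spectrum()].
#' @param path_scale Positive dimensionless path-length scaling.
#' @return A [spectrum()] whose `absorbance` column is replaced by a
#'   `transmittance` column on the 0-1 scale.
#' @export
absorbance_to_transmittance <- function(s, path_scale = 1) {
  s <- validate_spectrum(s)
  stopifnot(path_scale > 0)
  tr <- pmin(pmax(10^(-s$absorbance * path_scale), 0), 1)
  out <- tibble::tibble(wavelength_nm = s$wavelength_nm, transmittance = tr)
  structure(out, class = c("transmittance_spectrum", class(tibble::tibble())),
            metadata = series_metadata(s))
}

#' Extend a transmittance or absorbance spectrum to the CIE range
#'
#' Colorimetric integration needs coverage of 380-780 nm. Spectra acquired
#' over a narrower window (e.g. 400-700 nm) can be explicitly padded:
#' absorbance is padded with `fill` (default 0, i.e. fully transmitting),
#' transmittance with `10^-fill`.
#'
#' @param s A [spectrum()] or transmittance spectrum.
#' @param range Target wavelength range.
#' @param fill Absorbance value assumed outside the measured support.
#' @return Object of the same type covering `range`.
#' @export
extend_to_cie_range <- function(s, range = c(380, 780), fill = 0) {
  is_tr <- inherits(s, "transmittance_spectrum")
  w <- s$wavelength_nm
  step <- stats::median(diff(w))
  pre <- rev(seq(min(w) - step, range[1], by = -step))
  post <- seq(max(w) + step, range[2], by = step)
  pre <- pre[pre >= range[1] - step / 2]
  post <- post[post <= range[2] + step / 2]
  val <- if (is_tr) 10^(-fill) else fill
  if (is_tr) {
    out <- tibble::tibble(
      wavelength_nm = c(pre, w, post),
      transmittance = c(rep(val, length(pre)), s$transmittance, rep(val, length(post))))
    structure(out, class = class(s), metadata = series_metadata(s))
  } else {
    spectrum(c(pre, w, post),
             c(rep(val, length(pre)), s$absorbance, rep(val, length(post))),
             metadata = series_metadata(s))
  }
}

#' Tristimulus integration of a transmittance spectrum
#'
#' X, Y, Z = k * sum T(lambda) S(lambda) cmf(lambda) dlambda with k chosen so
#' that a perfect transmitter (T = 1) has Y = 100 under the configured
#' illuminant.
#'
#' @param t A transmittance spectrum from [absorbance_to_transmittance()],
#'   covering 380-780 nm (see [extend_to_cie_range()]).
#' @param settings A [colorimetry_settings()].
#' @return One-row tibble with columns `X`, `Y`, `Z`.
#' @export
spectrum_to_xyz <- function(t, settings = colorimetry_settings()) {
  if (!inherits(t, "transmittance_spectrum")) {
    rlang::abort("`t` must be a transmittance spectrum (see absorbance_to_transmittance())")
  }
  if (min(t$wavelength_nm) > 380 || max(t$wavelength_nm) < 780) {
    rlang::abort(sprintf(
      "transmittance covers [%g, %g] nm but colorimetry needs 380-780 nm; see extend_to_cie_range()",
      min(t$wavelength_nm), max(t$wavelength_nm)))
  }
  tab <- cie_tables(settings$observer, settings$illuminant, settings$step_nm)
  tr <- stats::approx(t$wavelength_nm, t$transmittance, xout = tab$wavelength_nm)$y
  k <- 100 / sum(tab$illuminant_power * tab$ybar)
  tibble::tibble(
    X = k * sum(tr * tab$illuminant_power * tab$xbar),
    Y = k * sum(tr * tab$illuminant_power * tab$ybar),
    Z = k * sum(tr * tab$illuminant_power * tab$zbar)
  )
}

#' Whitepoint of the configured illuminant
#' @param settings A [colorimetry_settings()].
#' @return Numeric length-3 `c(X, Y, Z)` with `Y = 100`.
#' @export
illuminant_whitepoint <- function(settings = colorimetry_settings()) {
  tab <- cie_tables(settings$observer, settings$illuminant, settings$step_nm)
  k <- 100 / sum(tab$illuminant_power * tab$ybar)
  c(X = k * sum(tab$illuminant_power * tab$xbar), Y = 100,
    Z = k * sum(tab$illuminant_power * tab$zbar))
}

#' CIE 1976 L*a*b* from tristimulus values
#'
#' Standard CIELAB formulas including the linear segment below (6/29)^3.
#'
#' @param xyz One-row tibble or numeric length-3 `c(X, Y, Z)`.
#' @param whitepoint Numeric length-3 reference white `c(Xn, Yn, Zn)`.
#' @return One-row tibble with `L_star`, `a_star`, `b_star`.
#' @export
xyz_to_lab <- function(xyz, whitepoint = illuminant_whitepoint()) {
  v <- if (is.data.frame(xyz)) c(xyz$X, xyz$Y, xyz$Z) else as.numeric(xyz)
  if (any(v < 0)) rlang::abort("XYZ components must be non-negative")
  if (any(whitepoint <= 0)) rlang::abort("whitepoint components must be positive")
  f <- function(u) {
    d <- 6 / 29
    ifelse(u > d^3, u^(1 / 3), u / (3 * d^2) + 4 / 29)
  }
  r <- unname(f(v / as.numeric(whitepoint)))
  tibble::tibble(
    L_star = 116 * r[2] - 16,
    a_star = 500 * (r[1] - r[2]),
    b_star = 200 * (r[2] - r[3])
  )
}

#' Hue angle and chroma in the a*b* plane
#'
#' h = atan2(b*, a*) mapped to \[0, 360) degrees; C* = sqrt(a*^2 + b*^2).
#' On the neutral axis (a* = b* = 0) hue is undefined and returned as `NA`
#' with `hue_defined = FALSE`.
#'
#' @param lab One-row tibble from [xyz_to_lab()] (or any data frame with
#'   `a_star`, `b_star`).
#' @return One-row tibble `hue_deg`, `chroma`, `hue_defined`.
#' @export
hue_chroma <- function(lab) {
  a <- lab$a_star; b <- lab$b_star
  chroma <- sqrt(a^2 + b^2)
  undef <- a == 0 & b == 0
  hue <- (atan2(b, a) * 180 / pi) %% 360
  hue[undef] <- NA_real_
  tibble::tibble(hue_deg = hue, chroma = chroma, hue_defined = !undef)
}

#' CIE76 colour difference
#'
#' Euclidean distance in L*a*b*. Hue matching between colorants is reported
#' alongside as the absolute hue-angle difference.
#'
#' @param x,y One-row tibbles with `L_star`, `a_star`, `b_star`.
#' @return Scalar delta-E*ab.
#' @export
delta_e76 <- function(x, y) {
  sqrt((x$L_star - y$L_star)^2 + (x$a_star - y$a_star)^2 + (x$b_star - y$b_star)^2)
}

#' Full colour report for one absorbance spectrum
#'
#' Chains Beer-Lambert transmittance, tristimulus integration, CIELAB and
#' hue/chroma into a single tidy row, the quantities used to compare a
#' candidate colorant with a reference shade.
#'
#' @param s An absorbance [spectrum()] (padded to 380-780 nm if needed).
#' @param settings A [colorimetry_settings()].
#' @param sample Sample label for the report.
#' @return One-row tibble: sample, XYZ, Lab, hue, chroma and settings fields.
#' @export
color_report <- function(s, settings = colorimetry_settings(), sample = NA_character_) {
  if (min(s$wavelength_nm) > 380 || max(s$wavelength_nm) < 780) {
    s <- extend_to_cie_range(s)
  }
  tr <- absorbance_to_transmittance(s, settings$path_scale)
  xyz <- spectrum_to_xyz(tr, settings)
  lab <- xyz_to_lab(xyz, illuminant_whitepoint(settings))
  hc <- hue_chroma(lab)
  dplyr::bind_cols(
    tibble::tibble(sample = sample), xyz, lab, hc,
    tibble::tibble(observer = settings$observer, illuminant = settings$illuminant)
  )
}
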