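make_transmittance <- function(wavelength, transmittance) {
  structure(tibble::tibble(wavelength_nm = wavelength, transmittance = transmittance),
            class = c("transmittance_spectrum", class(tibble::tibble())))
}

test_that("Beer-Lambert transmittance follows 10^(-A * path) with clipping", {
  g <- 380:780
  s0 <- spectrum(g, rep(0, length(g)))
  expect_true(all(absorbance_to_transmittance(s0)$transmittance == 1))
  s1 <- spectrum(g, rep(1, length(g)))
  expect_equal(absorbance_to_transmittance(s1)$transmittance,
               rep(0.1, length(g)))
  s05 <- spectrum(g, rep(0.5, length(g)))
  expect_equal(absorbance_to_transmittance(s05, path_scale = 2)$transmittance,
               rep(0.1, length(g)))
  # negative baseline noise would give T > 1; clipped to physical range
  sneg <- spectrum(g, rep(-0.2, length(g)))
  expect_true(all(absorbance_to_transmittance(sneg)$transmittance == 1))
})

test_that("tristimulus integration normalises the perfect transmitter to Y = 100", {
  g <- 380:780
  white <- spectrum_to_xyz(make_transmittance(g, rep(1, length(g))))
  wp <- illuminant_whitepoint()
  expect_equal(white$Y, 100)
  expect_equal(c(white$X, white$Y, white$Z), unname(wp), tolerance = 1e-12)

  black <- spectrum_to_xyz(make_transmittance(g, rep(0, length(g))))
  expect_equal(c(black$X, black$Y, black$Z), c(0, 0, 0))

  expect_error(spectrum_to_xyz(make_transmittance(400:700, rep(1, 301))), "380-780")
})

test_that("tristimulus values match an independent summation within 0.1%", {
  g <- 380:780
  for (center in c(460, 560, 640)) {
    tr <- exp(-(g - center)^2 / (2 * 12^2))
    got <- spectrum_to_xyz(make_transmittance(g, tr))
    want <- xyz_riemann_oracle(g, tr)
    expect_equal(c(got$X, got$Y, got$Z), unname(want), tolerance = 1e-3)
  }
})

test_that("CIELAB conversion matches the grDevices implementation to 1e-6", {
  wp <- grdevices_d65_whitepoint()
  expect_equal(as.numeric(xyz_to_lab(wp, wp)), c(100, 0, 0))
  expect_equal(xyz_to_lab(c(10, 0, 5), wp)$L_star, 0)

  set.seed(21)
  for (i in 1:20) {
    xyz <- runif(3, 0, 99)
    got <- xyz_to_lab(xyz, wp)
    want <- grDevices::convertColor(matrix(xyz / 100, 1), from = "XYZ", to = "Lab")
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-6)
  }
  expect_error(xyz_to_lab(c(-1, 50, 50), wp), "non-negative")
})

test_that("hue angle and chroma follow atan2 geometry with a flagged neutral axis", {
  lab <- function(a, b) tibble::tibble(L_star = 50, a_star = a, b_star = b)
  expect_equal(hue_chroma(lab(1, 0))$hue_deg, 0)
  expect_equal(hue_chroma(lab(1, 0))$chroma, 1)
  expect_equal(hue_chroma(lab(0, -1))$hue_deg, 270)
  hc <- hue_chroma(lab(-3, 4))
  expect_equal(hc$chroma, 5)
  expect_equal(hc$hue_deg, atan2(4, -3) * 180 / pi)

  neutral <- hue_chroma(lab(0, 0))
  expect_true(is.na(neutral$hue_deg))
  expect_false(neutral$hue_defined)

  # rotating (a*, b*) by phi shifts hue by exactly phi mod 360
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(1, sd = 20); b <- rnorm(1, sd = 20); phi <- runif(1, 0, 360)
    h0 <- hue_chroma(lab(a, b))$hue_deg
    rad <- phi * pi / 180
    h1 <- hue_chroma(lab(a * cos(rad) - b * sin(rad),
                         a * sin(rad) + b * cos(rad)))$hue_deg
    expect_equal((h1 - h0) %% 360, phi %% 360, tolerance = 1e-8)
  }
})

test_that("CIE76 colour difference is a metric", {
  lab <- function(v) tibble::tibble(L_star = v[1], a_star = v[2], b_star = v[3])
  expect_equal(delta_e76(lab(c(50, 10, -10)), lab(c(50, 10, -10))), 0)
  expect_equal(delta_e76(lab(c(0, 0, 0)), lab(c(100, 0, 0))), 100)
  set.seed(9)
  for (i in 1:25) {
    x <- lab(runif(3, -50, 100)); y <- lab(runif(3, -50, 100))
    z <- lab(runif(3, -50, 100))
    expect_equal(delta_e76(x, y), delta_e76(y, x))
    expect_gte(delta_e76(x, y) + delta_e76(y, z), delta_e76(x, z))
  }
})

test_that("narrow transmission windows sweep hue monotonically from blue toward red", {
  g <- 380:780
  hues <- vapply(seq(440, 640, by = 10), function(center) {
    tr <- exp(-(g - center)^2 / (2 * 15^2))
    lab <- xyz_to_lab(spectrum_to_xyz(make_transmittance(g, tr)))
    hue_chroma(lab)$hue_deg
  }, numeric(1))
  expect_true(all(diff(hues) < 0))
  # the sweep passes from blue (> 250 deg) through cyan (~200 deg)
  expect_gt(hues[1], 250)
  expect_true(any(hues > 180 & hues < 230))
})

test_that("color_report pads visible-range spectra and carries settings", {
  rep <- color_report(make_spectrum_fixture("alp2_pH7"), sample = "alp2")
  expect_equal(rep$sample, "alp2")
  expect_true(rep$L_star > 0 && rep$L_star <= 100)
  expect_true(rep$hue_defined)
  # a cyan colorant sits in the blue-green quadrant (a* < 0, b* < 0)
  expect_lt(rep$a_star, 0)
  expect_lt(rep$b_star, 0)
  expect_equal(rep$illuminant, "D65")
})
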