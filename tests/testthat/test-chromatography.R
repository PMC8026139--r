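single_peak <- function(apex = 10, sigma = 0.2, area = 50, noise = 0, seed = 1) {
  tm <- seq(5, 15, by = 0.01)
  sig <- area / (sigma * sqrt(2 * pi)) * exp(-(tm - apex)^2 / (2 * sigma^2))
  if (noise > 0) { set.seed(seed); sig <- sig + rnorm(length(sig), 0, noise) }
  chromatogram(tm, sig)
}

test_that("peak detection finds isolated peaks and ignores flat traces", {
  ch <- single_peak(apex = 10)
  p <- detect_peaks(ch)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$apex_time_min - 10), 0.011)

  flat <- chromatogram(seq(0, 10, by = 0.01), rep(0, 1001))
  expect_equal(nrow(detect_peaks(flat)), 0)

  rca <- make_rca_chromatogram("untreated")
  p8 <- detect_peaks(rca)
  expect_equal(nrow(p8), 8)
  expect_true(!is.unsorted(p8$apex_time_min))
  expect_equal(p8$apex_time_min, rca_reference_times()$time_min, tolerance = 0.011)
})

test_that("peak detection is invariant under uniform scaling with scaled thresholds", {
  ch <- make_rca_chromatogram("untreated")
  base <- detect_peaks(ch, min_height = 1, min_prominence = 0.5)
  scaled <- chromatogram(ch$time_min, ch$signal * 37)
  p <- detect_peaks(scaled, min_height = 37, min_prominence = 0.5 * 37)
  expect_equal(p$apex_time_min, base$apex_time_min)
  expect_equal(p$start_time_min, base$start_time_min)
})

test_that("integration recovers known Gaussian areas above a valley baseline", {
  ch <- single_peak(apex = 10, sigma = 0.2, area = 50)
  p <- integrate_peaks(ch, detect_peaks(ch))
  expect_lt(abs(p$area - 50) / 50, 0.01)
  expect_equal(p$relative_area, 100)

  # two identical peaks split the area 50/50
  tm <- seq(0, 20, by = 0.01)
  sig <- dnorm(tm, 6, 0.2) + dnorm(tm, 14, 0.2)
  p2 <- integrate_peaks(chromatogram(tm, sig), detect_peaks(chromatogram(tm, sig)))
  expect_equal(p2$relative_area, c(50, 50), tolerance = 1e-6)
})

test_that("relative areas sum to 100 and assignment conserves areas", {
  ch <- make_rca_chromatogram("WT_partial")
  p <- integrate_peaks(ch, detect_peaks(ch))
  expect_equal(sum(p$relative_area), 100, tolerance = 1e-6)
  assigned <- assign_peaks(p)
  expect_equal(assigned$area, p$area)
  expect_equal(sum(assigned$relative_area), 100, tolerance = 1e-6)
})

test_that("the untreated fixture puts P2 below the 5% natural-abundance bound", {
  ch <- make_rca_chromatogram("untreated")
  p <- assign_peaks(integrate_peaks(ch, detect_peaks(ch)))
  p2 <- p$relative_area[p$peak == "P2"]
  expect_lt(p2, 5)
  expect_equal(p2, 4, tolerance = 0.2)
  # integrated areas reproduce the generator truth within 1%
  truth <- attr(ch, "metadata")$true_relative_areas
  expect_equal(p$relative_area[match(names(truth), p$peak)], unname(truth),
               tolerance = 0.01)
})

test_that("peak assignment is nearest-reference with tolerance and conflict resolution", {
  ch <- make_rca_chromatogram("untreated")
  p <- assign_peaks(integrate_peaks(ch, detect_peaks(ch)))
  expect_equal(p$peak, paste0("P", 1:8))

  expect_equal(nrow(assign_peaks(integrate_peaks(ch, detect_peaks(
    chromatogram(seq(0, 5, 0.01), rep(0, 501)))))), 0)

  # a peak shifted past the tolerance stays unassigned
  shifted <- chromatogram(ch$time_min + 0.6, ch$signal)
  ps <- assign_peaks(integrate_peaks(shifted, detect_peaks(shifted)),
                     rca_reference_times()[1, ], tol_min = 0.5)
  expect_true(all(ps$peak == "unassigned"))

  # two peaks near one reference: the nearer wins
  tm <- seq(10, 14, by = 0.01)
  sig <- dnorm(tm, 11.9, 0.05) + dnorm(tm, 12.3, 0.05)
  pp <- assign_peaks(integrate_peaks(chromatogram(tm, sig),
                                     detect_peaks(chromatogram(tm, sig))),
                     rca_reference_times()[1, ], tol_min = 0.5)
  expect_equal(pp$peak, c("P1", "unassigned"))
})

test_that("conversion metrics quantify the esterase transformation", {
  before <- assign_peaks(integrate_peaks(make_rca_chromatogram("untreated"),
                                         detect_peaks(make_rca_chromatogram("untreated"))))
  # identity: nothing converted
  same <- conversion_metrics(before, before)
  expect_equal(same$fraction_converted, 0)
  expect_false(same$complete)

  after <- assign_peaks(integrate_peaks(make_rca_chromatogram("M73H_complete"),
                                        detect_peaks(make_rca_chromatogram("M73H_complete"))))
  conv <- conversion_metrics(before, after)
  expect_gte(conv$fraction_converted, 0.99)
  expect_true(conv$complete)
  expect_gt(conv$P1_plus_P2_relative_area_after, 99)

  # half of the P6-P8 area moved by the generator
  half <- assign_peaks(integrate_peaks(make_rca_chromatogram("WT_partial"),
                                       detect_peaks(make_rca_chromatogram("WT_partial"))))
  expect_equal(conversion_metrics(before, half)$fraction_P6toP8_converted, 0.5,
               tolerance = 0.01)
})
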