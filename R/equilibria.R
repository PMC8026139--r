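#' Flavylium multistate parameters
#'
#' The anthocyanin multistate is lumped into three pools: the red flavylium
#' cation AH+, the colored quinoidal base A (deprotonation, pKa) and the
#' colorless hydrated forms B/C (hemiketal plus chalcones, apparent hydration
#' constant pK'h). Higher pK'h means better resistance to fading by water
#' addition at C2.
#'
#' @param pKa Acid-base constant (log units); `Inf` disables deprotonation.
#' @param pKh_prime Apparent hydration constant (log units).
#' @return A list of class `"multistate_params"`.
#' @export
multistate_params <- function(pKa = Inf, pKh_prime) {
  if (!is.finite(pKh_prime)) rlang::abort("pKh_prime must be finite")
  for (v in c(pKa = pKa, pKh_prime = pKh_prime)) {
    if (is.finite(v) && (v < 0 || v > 10)) {
      rlang::warn(sprintf("constant %.3g outside the typical 0-10 range", v))
    }
  }
  structure(list(pKa = pKa, pKh_prime = pKh_prime), class = "multistate_params")
}

#' Fraction of colored anthocyanin forms at a given pH
#'
#' Colored fraction (flavylium + quinoidal base) out of the full multistate:
#' (1 + 10^(pH - pKa)) / (1 + 10^(pH - pKa) + 10^(pH - pK'h)).
#' Monotone non-increasing in pH and bounded in \[0, 1\].
#'
#' @param pH Numeric vector of pH values.
#' @param params A [multistate_params()].
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' p <- multistate_params(pKa = Inf, pKh_prime = 4.4)
#' colored_fraction(4.4, p) # 0.5
#' @export
colored_fraction <- function(pH, params) {
  qa <- if (is.finite(params$pKa)) 10^(pH - params$pKa) else 0
  hy <- 10^(pH - params$pKh_prime)
  (1 + qa) / (1 + qa + hy)
}

#' Simulate an equilibrium pH-titration series
#'
#' A(pH) = A0 * colored_fraction(pH) plus i.i.d. Gaussian noise, emulating
#' endpoint absorbances of a pH-jump series at fixed wavelength. The seed is
#' applied locally and recorded in the metadata; the same seed reproduces the
#' series bit for bit.
#'
#' @param params A [multistate_params()].
#' @param pH_grid Increasing pH values.
#' @param A0 Absorbance of the fully colored solution (AU), > 0.
#' @param noise_sd Gaussian noise standard deviation (AU), >= 0.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble of class `"titration_series"` with columns `pH`,
#'   `absorbance`.
#' @export
simulate_titration <- function(params, pH_grid = seq(0.5, 6.5, length.out = 26),
                               A0 = 1, noise_sd = 0, seed = NULL) {
  stopifnot(A0 > 0, noise_sd >= 0, !is.unsorted(pH_grid, strictly = TRUE))
  mu <- A0 * colored_fraction(pH_grid, params)
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) rlang::abort("a seed is required for noisy simulation")
    local_rng(seed, stats::rnorm(length(mu), 0, noise_sd))
  } else rep(0, length(mu))
  out <- tibble::tibble(pH = as.numeric(pH_grid), absorbance = mu + noise)
  structure(out, class = c("titration_series", class(tibble::tibble())),
            metadata = list(params = unclass(params), A0 = A0,
                            noise_sd = noise_sd, seed = seed))
}

# evaluate expr under a local RNG state so no global seed is disturbed
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the apparent hydration constant pK'h from titration data
#'
#' Nonlinear least squares of the restricted hydration sigmoid
#' A(pH) = A0 / (1 + 10^(pH - pK'h)), the acidic-regime model in which the
#' quinoidal base is negligible. Starting values are data driven: pK'h at the
#' pH of half-maximal absorbance, A0 at the maximum absorbance.
#'
#' @param data A data frame with columns `pH` and `absorbance`, at least 5
#'   points spanning the transition.
#' @param start Optional named list `list(A0 =, pKh =)` overriding the
#'   data-driven starting values.
#' @return An object of class `"pkh_fit"`: estimates, standard errors, 95%
#'   confidence intervals, convergence flag and the underlying `nls` fit.
#'   Use [tidy()] / [glance()] for tabular access.
#' @examples
#' d <- simulate_titration(multistate_params(pKh_prime = 4.4))
#' fit_pkh(d)$estimate
#' @export
fit_pkh <- function(data, start = NULL) {
  stopifnot(all(c("pH", "absorbance") %in% names(data)))
  if (nrow(data) < 5) rlang::abort("need at least 5 titration points")
  if (is.null(start)) {
    A0_0 <- max(data$absorbance)
    half <- A0_0 / 2
    i <- which.min(abs(data$absorbance - half))
    start <- list(A0 = A0_0, pKh = data$pH[i])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(absorbance ~ A0 / (1 + 10^(pH - pKh)), data = data,
                      start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) rlang::abort(
      sprintf("pK'h fit did not converge (start A0=%.3g, pKh=%.3g): %s",
              start$A0, start$pKh, conditionMessage(e)))
  )
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  span_warn <- data$pH[1] > est["pKh"] || data$pH[nrow(data)] < est["pKh"] ||
    se["pKh"] > 0.5
  structure(list(
    estimate = unname(est["pKh"]), A0 = unname(est["A0"]),
    stderr = unname(se["pKh"]), stderr_A0 = unname(se["A0"]),
    ci95 = unname(ci["pKh", ]), n = nrow(data),
    converged = fit$convInfo$isConv %||% TRUE,
    transition_spanned = !span_warn,
    fit = fit
  ), class = "pkh_fit")
}

#' @export
print.pkh_fit <- function(x, ...) {
  cat(sprintf("Hydration fit: pK'h = %.3f (SE %.3f, 95%% CI %.3f-%.3f), A0 = %.4f, n = %d\n",
              x$estimate, x$stderr, x$ci95[1], x$ci95[2], x$A0, x$n))
  if (!x$transition_spanned) cat("warning: transition poorly spanned; wide CI\n")
  invisible(x)
}
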