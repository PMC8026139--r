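#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pkh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pKh_prime", "A0"),
    estimate = c(x$estimate, x$A0),
    std.error = c(x$stderr, x$stderr_A0),
    conf.low = c(x$ci95[1], x$A0 - 1.96 * x$stderr_A0),
    conf.high = c(x$ci95[2], x$A0 + 1.96 * x$stderr_A0)
  )
}

#' @export
glance.pkh_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, converged = x$converged,
                 transition_spanned = x$transition_spanned,
                 sigma = if (!is.null(x$fit)) summary(x$fit)$sigma else NA_real_)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("k_per_day", "A0"),
                 estimate = c(x$k_per_day, x$A0))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, converged = x$converged,
                 half_life_days = x$half_life_days)
}

#' @export
tidy.stoich_assignment <- function(x, ...) x$assignments

#' @export
glance.stoich_assignment <- function(x, ...) {
  tibble::tibble(n_observed = x$n_observed, tol_ppm = x$tol_ppm,
                 consensus_k = x$consensus_k,
                 n_candidates = nrow(x$assignments))
}
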