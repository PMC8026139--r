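# Independent oracles used across the suite. Each is deliberately coded
# from first principles, separate from the package implementation paths it
# checks.

# fine-grid trapezoid quadrature of a function sampled by linear interpolation
trapezoid_integral <- function(w, a, lo, hi, step = 0.1) {
  g <- seq(lo, hi, by = step)
  y <- approx(w, a, xout = g)$y
  sum((head(y, -1) + tail(y, -1)) / 2) * step
}

# explicit-loop tristimulus summation (second implementation of the CIE
# integration) from the packaged tables
xyz_riemann_oracle <- function(wavelength, transmittance, settings = colorimetry_settings()) {
  tab <- cie_tables(settings$observer, settings$illuminant, settings$step_nm)
  tr <- approx(wavelength, transmittance, xout = tab$wavelength_nm)$y
  num <- c(X = 0, Y = 0, Z = 0); den <- 0
  for (i in seq_len(nrow(tab))) {
    s <- tab$illuminant_power[i]
    num["X"] <- num["X"] + tr[i] * s * tab$xbar[i]
    num["Y"] <- num["Y"] + tr[i] * s * tab$ybar[i]
    num["Z"] <- num["Z"] + tr[i] * s * tab$zbar[i]
    den <- den + s * tab$ybar[i]
  }
  100 * num / den
}

# the grDevices Lab conversion uses D65 chromaticity (0.3137, 0.3291);
# matching whitepoint on the Y=100 scale for cross-implementation checks
grdevices_d65_whitepoint <- function() {
  x <- 0.3137; y <- 0.3291
  c(X = x / y * 100, Y = 100, Z = (1 - x - y) / y * 100)
}

# full-network flavylium speciation by explicit species enumeration:
# relative concentrations [AH+] = 1, [A] = 10^(pH-pKa), [B+C] = 10^(pH-pKh)
colored_fraction_enumeration <- function(pH, pKa, pKh) {
  flavylium <- 1
  quinoidal <- if (is.finite(pKa)) 10^(pH - pKa) else 0
  hydrated <- 10^(pH - pKh)
  total <- flavylium + quinoidal + hydrated
  (flavylium + quinoidal) / total
}

# exhaustive grid search for the hydration sigmoid, profiling A0 in closed
# form at each candidate pKh
grid_search_pkh <- function(data, pkh_grid = seq(0, 8, by = 1e-3)) {
  best <- c(pKh = NA_real_, A0 = NA_real_, sse = Inf)
  for (pkh in pkh_grid) {
    m <- 1 / (1 + 10^(data$pH - pkh))
    A0 <- sum(data$absorbance * m) / sum(m^2)
    sse <- sum((data$absorbance - A0 * m)^2)
    if (sse < best["sse"]) best <- c(pKh = pkh, A0 = A0, sse = sse)
  }
  best
}

# exhaustive global-alignment oracle for tiny sequences: enumerates every
# monotone alignment path with affine gap scoring (BLOSUM62, open 10,
# extend 1 -- opening costs open+extend as in the Biostrings convention)
# and returns the optimal score plus the identity of each optimal alignment
brute_global_alignments <- function(a, b, open = 10, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  results <- list()
  recurse <- function(i, j, score, cols_a, cols_b, state) {
    if (i > length(av) && j > length(bv)) {
      results[[length(results) + 1]] <<- list(score = score,
                                              a = cols_a, b = cols_b)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, score + B[av[i], bv[j]],
              c(cols_a, av[i]), c(cols_b, bv[j]), "m")
    }
    if (i <= length(av)) {
      pen <- if (state == "ga") extend else open + extend
      recurse(i + 1, j, score - pen, c(cols_a, av[i]), c(cols_b, "-"), "ga")
    }
    if (j <= length(bv)) {
      pen <- if (state == "gb") extend else open + extend
      recurse(i, j + 1, score - pen, c(cols_a, "-"), c(cols_b, bv[j]), "gb")
    }
  }
  recurse(1, 1, 0, character(), character(), "m")
  scores <- vapply(results, `[[`, numeric(1), "score")
  opt <- which(scores == max(scores))
  identities <- vapply(results[opt], function(r) {
    100 * sum(r$a == r$b & r$a != "-") / length(r$a)
  }, numeric(1))
  list(score = max(scores), identities = identities)
}

# sort-based median of the upper-triangle entries of an identity matrix
sorted_median_oracle <- function(m, ids = rownames(m)) {
  mm <- unclass(m)[ids, ids, drop = FALSE]
  v <- sort(mm[upper.tri(mm)])
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
}

# the default 46-enzyme panel and its identity matrix are expensive;
# compute once per test run
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- make_sequence_panel(seed = 7)
      cache <<- list(panel = panel, matrix = identity_matrix(panel))
    }
    cache
  }
})
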