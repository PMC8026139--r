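# Monoisotopic (most-abundant-isotope) atomic masses, Da, and the electron
# mass. CODATA/IUPAC values; enough elements for anthocyanins, common
# heteroatoms and the metals used in complexation work.
element_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  Mg = 23.9850417,
  Al = 26.98153853,
  P  = 30.97376163,
  S  = 31.97207100,
  K  = 38.96370668,
  Fe = 55.9349375
)
electron_mass <- 0.000548579909

#' Molecular formula with charge
#'
#' Element-count algebra over non-negative integer counts plus a signed
#' charge. Formulas add with `+` and subtract with `-`; subtraction that
#' would drive any count negative is an error.
#'
#' @param counts Named integer vector, e.g. `c(C = 44, H = 51, O = 25)`, or a
#'   formula string such as `"C44H51O25"`.
#' @param charge Signed integer charge.
#' @return Object of class `"molformula"`.
#' @examples
#' p2 <- molecular_formula("C44H51O25", charge = 1)
#' monoisotopic_mass(p2)
#' @export
molecular_formula <- function(counts, charge = 0) {
  if (is.character(counts)) counts <- parse_formula_counts(counts)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  counts <- counts[counts != 0]
  if (length(counts) == 0) rlang::abort("a formula needs at least one element")
  if (any(counts < 0)) rlang::abort("element counts must be non-negative")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    rlang::abort("counts must be a named vector of element symbols")
  }
  counts <- counts[order(match(names(counts), c("C", "H", setdiff(sort(names(counts)), c("C", "H")))))]
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "molformula")
}

parse_formula_counts <- function(x) {
  x <- gsub("\\s", "", x)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(gsub("[+-][0-9]*$", "", x))) {
    rlang::abort(sprintf("cannot parse formula '%s'", x))
  }
  sym <- gsub("[0-9]", "", parts)
  n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", parts)))
  n[is.na(n)] <- 1L
  c(tapply(n, sym, sum)[unique(sym)])
}

#' @export
format.molformula <- function(x, ...) {
  body <- paste0(names(x$counts),
                 ifelse(x$counts == 1, "", x$counts), collapse = "")
  ch <- if (x$charge == 0) "" else sprintf("%+d", x$charge)
  paste0(body, ch)
}

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula>", format(x), "\n")
  invisible(x)
}

#' @export
`+.molformula` <- function(e1, e2) {
  sym <- union(names(e1$counts), names(e2$counts))
  n <- (e1$counts[sym] %|0|% 0) + (e2$counts[sym] %|0|% 0)
  names(n) <- sym
  molecular_formula(n, e1$charge + e2$charge)
}

#' @export
`-.molformula` <- function(e1, e2) {
  sym <- union(names(e1$counts), names(e2$counts))
  n <- (e1$counts[sym] %|0|% 0) - (e2$counts[sym] %|0|% 0)
  names(n) <- sym
  if (any(n < 0)) {
    rlang::abort(sprintf("subtraction yields negative count for %s",
                         paste(sym[n < 0], collapse = ", ")))
  }
  molecular_formula(n, e1$charge - e2$charge)
}

`%|0|%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Monoisotopic mass of a formula (ion masses include electrons)
#'
#' Sum of most-abundant-isotope masses minus charge times the electron mass,
#' so cations are lighter and anions heavier than the neutral atom sum.
#' At the 10-ppm accuracy of external-calibration ESI-TOF work near
#' m/z 1000, the electron mass is not negligible.
#'
#' @param f A [molecular_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(molecular_formula(c(H = 2, O = 1))) # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  unknown <- setdiff(names(f$counts), names(element_masses))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("no packaged mass for element(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  sum(f$counts * element_masses[names(f$counts)]) - f$charge * electron_mass
}
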