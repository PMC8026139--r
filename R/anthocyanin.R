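# Residue increments for anthocyanin assembly. Glycosylation and acylation
# are condensations, so each residue is the free unit minus one water:
# glucosyl C6H10O5; p-coumaroyl C9H6O2; feruloyl C10H8O3; sinapoyl C11H10O4.
# The chromophore is the cyanidin flavylium cation C15H11O6+.
residue_formulas <- list(
  cyanidin     = list(counts = c(C = 15, H = 11, O = 6), charge = 1L),
  glucosyl     = list(counts = c(C = 6, H = 10, O = 5), charge = 0L),
  `p-coumaroyl` = list(counts = c(C = 9, H = 6, O = 2), charge = 0L),
  feruloyl     = list(counts = c(C = 10, H = 8, O = 3), charge = 0L),
  sinapoyl     = list(counts = c(C = 11, H = 10, O = 4), charge = 0L)
)

#' Anthocyanin building-block residues
#'
#' The condensed-residue formulas used by [compose_anthocyanin()]: the
#' cyanidin flavylium core and the glucosyl and hydroxycinnamoyl increments
#' (each already net of the water lost on condensation).
#'
#' @return Tibble with columns `residue`, `formula`, `monoisotopic_mass_da`.
#' @export
building_blocks <- function() {
  tibble::tibble(
    residue = names(residue_formulas),
    formula = vapply(residue_formulas, function(r)
      format(molecular_formula(r$counts, r$charge)), character(1)),
    monoisotopic_mass_da = vapply(residue_formulas, function(r)
      monoisotopic_mass(molecular_formula(r$counts, r$charge)), numeric(1))
  )
}

#' Specify an anthocyanin by its building blocks
#'
#' Red-cabbage anthocyanins share a cyanidin chromophore with a sophorose at
#' position 3 and a glucose at position 5 (three glucosyl residues in total);
#' they differ in hydroxycinnamoyl acylation of Glc-1 or Glc-2 of the
#' sophorose.
#'
#' @param core Chromophore identifier; only `"cyanidin"` is packaged.
#' @param n_glucosyl Number of glycosyl residues (>= 1).
#' @param acyl_groups Character vector over `p-coumaroyl`, `feruloyl`,
#'   `sinapoyl`, optionally named by position (`Glc-1`, `Glc-2`).
#' @return Object of class `"anthocyanin_spec"`.
#' @export
anthocyanin_spec <- function(core = "cyanidin", n_glucosyl = 3,
                             acyl_groups = character()) {
  if (!identical(core, "cyanidin")) {
    rlang::abort(sprintf("unknown chromophore '%s' (packaged: cyanidin)", core))
  }
  if (n_glucosyl < 1) rlang::abort("n_glucosyl must be >= 1")
  bad <- setdiff(acyl_groups, c("p-coumaroyl", "feruloyl", "sinapoyl"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown acyl residue(s): %s", paste(bad, collapse = ", ")))
  }
  pos <- names(acyl_groups)
  if (!is.null(pos) && length(pos) > 0) {
    badpos <- setdiff(pos[nzchar(pos)], c("Glc-1", "Glc-2"))
    if (length(badpos) > 0) {
      rlang::abort(sprintf("invalid acyl position(s): %s", paste(badpos, collapse = ", ")))
    }
  }
  structure(list(core = core, n_glucosyl = as.integer(n_glucosyl),
                 acyl_groups = acyl_groups),
            class = "anthocyanin_spec")
}

#' Compose the flavylium-cation formula of an anthocyanin
#'
#' Residue arithmetic on the condensed building blocks; the result carries
#' the +1 charge of the flavylium chromophore. P2 (cyanidin + 3 glucosyl +
#' 1 sinapoyl) composes to C44H51O25+.
#'
#' @param spec An [anthocyanin_spec()] (a bare spec list is also accepted).
#' @return A [molecular_formula()] with charge +1.
#' @examples
#' p2 <- compose_anthocyanin(anthocyanin_spec(n_glucosyl = 3, acyl_groups = "sinapoyl"))
#' format(p2) # "C44H51O25+1"
#' @export
compose_anthocyanin <- function(spec) {
  res <- function(nm) molecular_formula(residue_formulas[[nm]]$counts,
                                        residue_formulas[[nm]]$charge)
  f <- res(spec$core)
  if (spec$n_glucosyl > 0) {
    for (i in seq_len(spec$n_glucosyl)) f <- f + res("glucosyl")
  }
  for (a in spec$acyl_groups) f <- f + res(a)
  f
}

#' Compositions of the red-cabbage anthocyanin peak series
#'
#' The P1-P8 series: cyanidin-3-sophoroside-5-glucoside (three glucosyl
#' residues) with zero, one or two hydroxycinnamoyl groups. Acyl identities
#' follow the structural homology of the series (P2 carries sinapoyl on
#' Glc-2; P3-P5 are monoacylated on Glc-1; P6-P8 are diacylated).
#'
#' @return Tibble: `peak_id`, `acylation`, `formula`, `cation_mz`.
#' @export
rca_anthocyanins <- function() {
  specs <- list(
    P1 = anthocyanin_spec(acyl_groups = character()),
    P2 = anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")),
    P3 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "p-coumaroyl")),
    P4 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "feruloyl")),
    P5 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "sinapoyl")),
    P6 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "p-coumaroyl", `Glc-2` = "sinapoyl")),
    P7 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "feruloyl", `Glc-2` = "sinapoyl")),
    P8 = anthocyanin_spec(acyl_groups = c(`Glc-1` = "sinapoyl", `Glc-2` = "sinapoyl"))
  )
  tibble::tibble(
    peak_id = names(specs),
    acylation = vapply(specs, function(s) {
      if (length(s$acyl_groups) == 0) "none"
      else paste(paste0(s$acyl_groups, " (", names(s$acyl_groups), ")"), collapse = ", ")
    }, character(1)),
    formula = vapply(specs, function(s) format(compose_anthocyanin(s)), character(1)),
    cation_mz = vapply(specs, function(s) monoisotopic_mass(compose_anthocyanin(s)), numeric(1))
  )
}
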