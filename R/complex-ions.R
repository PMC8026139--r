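#' m/z of a multivalent metal-anthocyanin complex ion
#'
#' The ion is built from `k` ligand units, an optional metal atom, and `n`
#' hydrogens removed, at charge `z`. Because bracket notations such as
#' "[3M+Al-2H]2-" are ambiguous about whether the ligand is counted as a
#' cation or a neutral base, the hydrogen-loss count is kept explicit and
#' can be searched over; mass is the ground truth. The ion mass is
#' sum of atomic masses minus z electrons (anions gain electrons), divided
#' by |z|.
#'
#' @param ligand A [molecular_formula()]; its atoms are counted as given and
#'   its own charge is ignored (hydrogen loss absorbs the convention).
#' @param k_ligands Number of ligand units (>= 1).
#' @param metal Element symbol (e.g. `"Al"`) or `NULL` for none.
#' @param n_hydrogens_removed Hydrogens removed from the assembly (>= 0).
#' @param z Signed, non-zero integer charge.
#' @return m/z in Th (scalar).
#' @examples
#' p2 <- molecular_formula("C44H51O25", charge = 1)
#' complex_ion_mz(p2, k_ligands = 3, metal = "Al", n_hydrogens_removed = 7, z = -2)
#' @export
complex_ion_mz <- function(ligand, k_ligands = 1, metal = NULL,
                           n_hydrogens_removed = 0, z = 1) {
  stopifnot(k_ligands >= 1, n_hydrogens_removed >= 0)
  if (z == 0) rlang::abort("charge z must be non-zero")
  h_total <- k_ligands * (ligand$counts["H"] %|0|% 0)
  if (n_hydrogens_removed > h_total) {
    rlang::abort(sprintf("removing %d hydrogens from %d available is impossible",
                         n_hydrogens_removed, h_total))
  }
  atoms <- k_ligands * sum(ligand$counts * element_masses[names(ligand$counts)])
  if (!is.null(metal)) {
    if (!metal %in% names(element_masses)) {
      rlang::abort(sprintf("no packaged mass for metal '%s'", metal))
    }
    atoms <- atoms + element_masses[[metal]]
  }
  m <- atoms - n_hydrogens_removed * element_masses[["H"]] - z * electron_mass
  unname(m / abs(z))
}

#' Assign metal-complex stoichiometry from observed exact masses
#'
#' Enumerates all combinations of ligand count `k`, hydrogen loss `n` and
#' charge `z` over a finite search space, computes each candidate m/z, and
#' keeps candidates within `tol_ppm` of each observed peak, ranked by
#' absolute ppm error. When several observed peaks agree on one ligand
#' count, that `k` is reported as the consensus stoichiometry (e.g. the
#' doubly and triply charged tri-ligand aluminium ions both pin k = 3).
#'
#' @param observed_mz Numeric vector of observed peak m/z values.
#' @param ligand A [molecular_formula()] for the ligand unit.
#' @param metal Element symbol or `NULL`.
#' @param tol_ppm Match tolerance in ppm (> 0, default 10: the
#'   external-calibration ESI-TOF regime).
#' @param k_range,n_range Integer search ranges (defaults 1-6 and 0-12).
#' @param z_range Signed charges to try (default both polarities, |z| 1-4).
#' @return Object of class `"stoich_assignment"`: a list with `assignments`
#'   (tibble `observed_mz`, `k`, `n`, `z`, `mz_calc`, `ppm_error`) and
#'   `consensus_k` (integer or `NA` if no single k matches all peaks).
#' @examples
#' p2 <- molecular_formula("C44H51O25", charge = 1)
#' assign_stoichiometry(c(1478.8629, 985.5760), p2, metal = "Al")$consensus_k
#' @export
assign_stoichiometry <- function(observed_mz, ligand, metal = NULL,
                                 tol_ppm = 10, k_range = 1:6, n_range = 0:12,
                                 z_range = c(-4:-1, 1:4)) {
  stopifnot(tol_ppm > 0, length(observed_mz) >= 1)
  grid <- tidyr::expand_grid(k = k_range, n = n_range, z = z_range)
  grid <- grid[grid$z != 0, ]
  grid$mz_calc <- purrr::pmap_dbl(grid, function(k, n, z) {
    if (n > k * (ligand$counts["H"] %|0|% 0)) return(NA_real_)
    complex_ion_mz(ligand, k_ligands = k, metal = metal,
                   n_hydrogens_removed = n, z = z)
  })
  hits <- purrr::map_dfr(observed_mz, function(mz) {
    ppm <- (grid$mz_calc - mz) / mz * 1e6
    keep <- !is.na(ppm) & abs(ppm) <= tol_ppm
    out <- grid[keep, ]
    out$observed_mz <- mz
    out$ppm_error <- ppm[keep]
    out
  })
  hits <- dplyr::arrange(
    dplyr::select(hits, "observed_mz", "k", "n", "z", "mz_calc", "ppm_error"),
    .data$observed_mz, abs(.data$ppm_error))
  matched_all <- table(factor(unique(hits[, c("observed_mz", "k")])$k,
                              levels = k_range))
  consensus <- as.integer(names(matched_all)[matched_all == length(observed_mz)])
  structure(list(
    assignments = tibble::as_tibble(hits),
    consensus_k = if (length(consensus) == 1) consensus else NA_integer_,
    candidate_k = consensus,
    n_observed = length(observed_mz),
    tol_ppm = tol_ppm
  ), class = "stoich_assignment")
}

#' @export
print.stoich_assignment <- function(x, ...) {
  cat(sprintf("Stoichiometry assignment over %d observed peak(s), tol %.3g ppm\n",
              x$n_observed, x$tol_ppm))
  if (nrow(x$assignments) == 0) {
    cat("no candidate within tolerance\n")
  } else {
    print(x$assignments)
    cat(if (is.na(x$consensus_k)) "no unique consensus ligand count\n"
        else sprintf("consensus ligand count k = %d (1:%d metal:ligand stoichiometry)\n",
                     x$consensus_k, x$consensus_k))
  }
  invisible(x)
}
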