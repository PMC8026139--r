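test_that("formula algebra is commutative, associative and refuses negatives", {
  f <- molecular_formula(c(C = 6, H = 12, O = 6))
  g <- molecular_formula(c(C = 2, H = 4, O = 2), charge = 1)
  h <- molecular_formula(c(H = 2, O = 1))
  expect_equal((f + g) + h, f + (g + h))
  expect_equal(f + g, g + f)
  expect_equal((f + g) - g, f)
  expect_error(h - f, "negative")
  expect_error(molecular_formula(c(C = -1)), "non-negative")
  expect_equal(format(molecular_formula("C44H51O25", charge = 1)), "C44H51O25+1")
  expect_equal(molecular_formula("C6H12O6")$counts,
               molecular_formula(c(C = 6, H = 12, O = 6))$counts)
})

test_that("monoisotopic masses use bundled isotope masses with electron correction", {
  expect_equal(monoisotopic_mass(molecular_formula(c(H = 2, O = 1))),
               18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(molecular_formula(c(Al = 1))),
               26.981539, tolerance = 1e-6)
  expect_error(monoisotopic_mass(molecular_formula(c(Xx = 1))), "Xx")

  # additivity over neutral formulas
  f <- molecular_formula(c(C = 10, H = 14, O = 3))
  g <- molecular_formula(c(C = 3, H = 7, N = 1, S = 1))
  expect_equal(monoisotopic_mass(f + g),
               monoisotopic_mass(f) + monoisotopic_mass(g), tolerance = 1e-12)

  # the electron correction separates a cation from its neutral composition
  neutral <- molecular_formula(c(C = 44, H = 51, O = 25))
  cation <- molecular_formula(c(C = 44, H = 51, O = 25), charge = 1)
  expect_equal(monoisotopic_mass(neutral) - monoisotopic_mass(cation),
               0.000548579909, tolerance = 1e-10)
})

test_that("anthocyanins compose from building blocks by residue arithmetic", {
  core <- compose_anthocyanin(anthocyanin_spec(n_glucosyl = 1))
  expect_equal(unname(core$counts[c("C", "H", "O")] -
                        molecular_formula("C6H10O5")$counts[c("C", "H", "O")]),
               c(15, 11, 6))
  expect_equal(core$charge, 1L)

  # oracle: independent residue sums for P2 and P8
  residues <- list(cyanidin = c(C = 15, H = 11, O = 6),
                   glucosyl = c(C = 6, H = 10, O = 5),
                   sinapoyl = c(C = 11, H = 10, O = 4))
  p2_counts <- residues$cyanidin + 3 * residues$glucosyl + residues$sinapoyl
  p2 <- compose_anthocyanin(anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")))
  expect_equal(unname(p2$counts[names(p2_counts)]), unname(p2_counts))
  expect_equal(format(p2), "C44H51O25+1")

  p8 <- compose_anthocyanin(anthocyanin_spec(
    acyl_groups = c(`Glc-1` = "sinapoyl", `Glc-2` = "sinapoyl")))
  expect_equal(format(p8), "C55H61O29+1")

  expect_error(anthocyanin_spec(acyl_groups = "malonyl"), "unknown acyl")
  expect_equal(monoisotopic_mass(p2), 979.2714, tolerance = 1e-4)
})

test_that("complex ion m/z reproduces the observed ESI-TOF peaks within 10 ppm", {
  p2 <- compose_anthocyanin(anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")))
  ppm <- function(calc, obs) abs(calc - obs) / obs * 1e6
  mz2 <- complex_ion_mz(p2, k_ligands = 3, metal = "Al",
                        n_hydrogens_removed = 7, z = -2)
  expect_lt(ppm(mz2, 1478.8629), 10)
  mz3 <- complex_ion_mz(p2, k_ligands = 3, metal = "Al",
                        n_hydrogens_removed = 8, z = -3)
  expect_lt(ppm(mz3, 985.5760), 10)

  # degenerate case: single ligand, no metal, no hydrogen loss
  expect_equal(complex_ion_mz(p2, z = 1), monoisotopic_mass(p2), tolerance = 1e-9)
  expect_equal(complex_ion_mz(p2, z = -2), monoisotopic_mass(
    molecular_formula(p2$counts, charge = -2)) / 2, tolerance = 1e-9)
  expect_error(complex_ion_mz(p2, n_hydrogens_removed = 60), "impossible")
  expect_error(complex_ion_mz(p2, z = 0), "non-zero")
})

test_that("stoichiometry search finds k = 3 as the unique consensus for the Al complex", {
  p2 <- compose_anthocyanin(anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")))
  res <- assign_stoichiometry(c(1478.8629, 985.5760), p2, metal = "Al")
  expect_equal(res$consensus_k, 3L)
  expect_equal(res$candidate_k, 3L)  # no other k matches both peaks
  expect_true(all(abs(res$assignments$ppm_error) <= 10))

  # self-match: the bare ligand cation assigns to k = 1, n = 0, z = +1
  res1 <- assign_stoichiometry(monoisotopic_mass(p2), p2, metal = NULL)
  top <- res1$assignments[1, ]
  expect_equal(c(top$k, top$n, top$z), c(1, 0, 1))

  # far-off mass: empty table, not an error
  none <- assign_stoichiometry(123.456, p2, metal = "Al")
  expect_equal(nrow(none$assignments), 0)
  expect_true(is.na(none$consensus_k))
})

test_that("randomised round-trips recover the true (k, n, z) as top hit", {
  p2 <- compose_anthocyanin(anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")))
  set.seed(77)
  # negative-mode data: the search polarity is fixed by the ionisation mode
  hits <- vapply(1:100, function(i) {
    k <- sample(1:6, 1); n <- sample(0:12, 1); z <- sample(-4:-1, 1)
    mz <- complex_ion_mz(p2, k, metal = "Al", n_hydrogens_removed = n, z = z)
    mz_jit <- mz * (1 + runif(1, -2e-6, 2e-6))
    top <- assign_stoichiometry(mz_jit, p2, metal = "Al",
                                z_range = -4:-1)$assignments[1, ]
    isTRUE(top$k == k && top$n == n && top$z == z)
  }, logical(1))
  expect_gte(sum(hits), 99)
})
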