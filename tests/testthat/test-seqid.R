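test_that("pairwise identity handles identical, near-identical and disjoint sequences", {
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 1), collapse = "")
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
})

test_that("identity agrees with the exhaustive small-alignment oracle", {
  cases <- list(c("ACDEFG", "ACDEYG"), c("AAAA", "CCCC"),
                c("WYKR", "WYR"), c("MKVL", "MKKVL"))
  for (cs in cases) {
    oracle <- brute_global_alignments(cs[1], cs[2])
    got <- pairwise_identity(cs[1], cs[2])
    expect_true(got %in% round(oracle$identities, 10) ||
                  any(abs(got - oracle$identities) < 1e-9),
                info = paste(cs, collapse = " vs "))
  }
  # the substitution-favourable pair has a unique gapless optimum
  o <- brute_global_alignments("ACDEFG", "ACDEYG")
  expect_equal(unique(o$identities), 100 * 5 / 6, tolerance = 1e-9)
})

test_that("identity is symmetric and 100 on the diagonal for any scheme", {
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aa, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(10:30, 1), TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 100)
  }
  # sequences over disjoint alphabets can never share an identical column
  expect_equal(pairwise_identity("ILVILVILV", "WYFWYFWYF"), 0)
  expect_equal(pairwise_identity("ILVILVILV", "WYFWYFWYF",
                                 identity_scheme(gap_opening = 2, gap_extension = 0.5)), 0)
})

test_that("identity matrices recompute pairwise calls and reject duplicate ids", {
  set.seed(14)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = replicate(3, paste(sample(aa, 25, TRUE), collapse = "")))
  m <- identity_matrix(recs)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(unclass(m))), rep(100, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], pairwise_identity(recs$sequence[i], recs$sequence[j]))
  }
  twin <- tibble::tibble(id = c("x", "y"), sequence = rep(recs$sequence[1], 2))
  expect_equal(identity_matrix(twin)[1, 2], 100)
  expect_error(identity_matrix(tibble::tibble(id = c("a", "a"),
                                              sequence = recs$sequence[1:2])),
               "duplicate")
})

test_that("median identity matches the sort-based oracle on subsets", {
  set.seed(15)
  n <- 8
  m <- matrix(runif(n * n, 0, 100), n)
  m <- (m + t(m)) / 2; diag(m) <- 100
  dimnames(m) <- list(letters[1:n], letters[1:n])
  m <- structure(m, class = c("identity_matrix", "matrix", "array"))
  expect_equal(median_identity(m), sorted_median_oracle(m))
  sub <- c("b", "d", "e", "g")
  expect_equal(median_identity(m, sub), sorted_median_oracle(m, sub))
  expect_equal(median_identity(m, c("a", "b")), m["a", "b"])
  expect_error(median_identity(m, c("a", "zz")), "zz")
  expect_error(median_identity(m, "a"), "at least 2")
})

test_that("screen summaries count tested and active enzymes", {
  panel <- make_sequence_panel(seed = 7)
  s <- screen_summary(panel)
  expect_equal(s$n_tested, 46L)
  expect_equal(s$n_active, 17L)
  expect_equal(s$fraction_active, 0.370)

  empty <- screen_summary(panel[0, ])
  expect_equal(c(empty$n_tested, empty$n_active), c(0L, 0L))
  expect_true(is.na(empty$fraction_active))

  allact <- panel[panel$active, ]
  expect_equal(screen_summary(allact)$fraction_active, 1)

  bad <- panel; bad$active[3] <- NA
  expect_error(screen_summary(bad), "enz03")
})

test_that("the synthetic esterase panel is seeded and clusters its active subset", {
  fix <- default_panel()
  panel <- fix$panel; m <- fix$matrix

  expect_identical(panel, make_sequence_panel(seed = 7))
  expect_false(identical(panel$sequence, make_sequence_panel(seed = 8)$sequence))

  # 46 records give 1035 unique off-diagonal pairs, all populated
  ut <- unclass(m)[upper.tri(unclass(m))]
  expect_equal(length(ut), 1035)
  expect_true(all(is.finite(ut)))

  # the active subset is more self-similar than the panel as a whole
  med_all <- median_identity(m)
  med_act <- median_identity(m, panel$id[panel$active])
  expect_gt(med_act, med_all)
})

test_that("panels round-trip through FASTA and export PHYLIP distances", {
  panel <- make_sequence_panel(n = 6, n_active = 3, seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(panel, fa)
  meta <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(panel[, c("id", "active", "ec_class")], meta, row.names = FALSE)
  back <- read_protein_panel(fa, meta)
  expect_equal(back$sequence, panel$sequence)
  expect_equal(back$active, panel$active)

  m <- identity_matrix(panel)
  dm <- withr::local_tempfile(fileext = ".dist")
  write_distance_matrix(m, dm)
  lines <- readLines(dm)
  expect_equal(as.integer(trimws(lines[1])), 6)
  first <- as.numeric(strsplit(trimws(sub("^\\S+\\s+", "", lines[2])), " ")[[1]])
  expect_equal(first, (100 - unclass(m)[1, ]) / 100, tolerance = 1e-6,
               ignore_attr = TRUE)
})
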