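test_that("variant codes parse, validate against the lead, and round-trip", {
  tnf1 <- lead_peptide("TNF1")
  v <- parse_variants("D4S", tnf1)
  expect_equal(v$position, 4L)
  expect_equal(v$wild, "D")
  expect_equal(v$sub, "S")

  v2 <- parse_variants("P6Y", lead_peptide("TRF26"))
  expect_equal(v2$position, 6L)
  expect_equal(v2$sub, "Y")

  # wild-letter mismatch flags a mislabeled table
  expect_error(parse_variants("D5S", tnf1), "has P")
  expect_error(parse_variants("4S", tnf1), "Malformed")
  expect_error(parse_variants("D18S", tnf1), "randomized region")

  # parse o format and format o parse are identities
  codes <- c("D4S", "P5Y", "M7K", "S11K", "F1Y")
  p <- parse_variants(codes, tnf1)
  expect_equal(format_variant(p$position, p$wild, p$sub), codes)
})

test_that("applying variant sets edits exactly the stated positions", {
  tnf1 <- lead_peptide("TNF1")
  expect_equal(
    apply_variants(tnf1, c("D4S", "P5Y", "M7K", "S11K"))$residues,
    "FERSYLKMPWKFLQSRQGSC"
  )
  expect_equal(apply_variants(tnf1, character(0))$residues, tnf1$residues)
  expect_equal(
    apply_variants(lead_peptide("TNF4"), c("Y1W", "D5Y", "T10Y"))$residues,
    "WGPSYAFKIYRFHQQSSGSC"
  )
  expect_error(apply_variants(tnf1, c("D4S", "D4Y")), "position")

  # order independence for disjoint positions
  set.seed(11)
  for (i in 1:10) {
    codes <- sample(c("F1Y", "E2K", "D4S", "P5Y", "M7K", "S11K"), 4)
    expect_equal(
      apply_variants(tnf1, codes)$residues,
      apply_variants(tnf1, rev(codes))$residues
    )
  }
})

test_that("library enumeration reproduces the combinatorial counts", {
  tnf1 <- lead_peptide("TNF1")
  lib <- enumerate_variants(tnf1)
  expect_equal(nrow(lib), 132L)
  expect_true(all(lib$wild != lib$sub))
  expect_false(anyDuplicated(lib$variant_code) > 0)

  lib323 <- enumerate_variants(lead_peptide("TRF26"),
                               alphabet = setdiff(amino_acids(), "C"),
                               mode = "include_identity")
  expect_equal(nrow(lib323), 323L)

  # alphabet equal to the lead residue at a single position -> empty
  empty <- enumerate_variants(tnf1, alphabet = "D", positions = 4)
  expect_equal(nrow(empty), 0L)

  # counts match brute-force enumeration on random small instances
  set.seed(42)
  for (i in 1:5) {
    alpha <- sample(amino_acids(), sample(2:6, 1))
    pos <- sort(sample(1:17, sample(2:5, 1)))
    lib_i <- enumerate_variants(tnf1, alphabet = alpha, positions = pos)
    brute <- 0L
    for (p in pos) for (a in alpha) {
      if (substr(tnf1$residues, p, p) != a) brute <- brute + 1L
    }
    expect_equal(nrow(lib_i), brute)
    inc <- enumerate_variants(tnf1, alphabet = alpha, positions = pos,
                              mode = "include_identity")
    expect_equal(nrow(inc), length(pos) * length(alpha))
  }

  expect_error(enumerate_variants(tnf1, positions = 18), "linker|randomized")
  expect_error(enumerate_variants(tnf1, alphabet = character(0)), "empty")
})

test_that("GRAVY reproduces the lead hydropathy scores and is a mean", {
  expect_equal(gravy(lead_peptide("TNF1"), digits = 2), -0.52)
  expect_equal(gravy(lead_peptide("TNF4"), digits = 2), -0.77)
  expect_equal(gravy("GGGG"), -0.4)

  # permutation invariance
  set.seed(7)
  s <- lead_peptide("TNF1")$residues
  for (i in 1:5) {
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gravy(perm), gravy(s))
  }
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 2 * 57.0519 + 18.01528, tolerance = 1e-9)
  # identity substitution leaves the mass unchanged
  tnf1 <- lead_peptide("TNF1")
  lib <- enumerate_variants(tnf1, alphabet = "D", positions = 4,
                            mode = "include_identity")
  expect_equal(lib$mw_da, molecular_weight(tnf1))
})

test_that("peptide construction enforces the canonical alphabet and linker", {
  expect_error(peptide("ABXDE"), "Non-canonical")
  expect_error(peptide(""), "non-empty")
  expect_error(peptide("GSC", linker_length = 3), "linker_length")
  p <- peptide("acdefgsc", name = "lower")
  expect_equal(p$residues, "ACDEFGSC")
  expect_equal(randomized_length(p), 5L)
})
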