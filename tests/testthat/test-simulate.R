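test_that("landscape construction enforces its invariants", {
  expect_error(
    energy_landscape(lead_peptide("TNF1"), -5.21,
                     tibble::tibble(position = 4L, residue = "D", ddg = -0.5)),
    "Identity"
  )
  expect_error(
    energy_landscape(lead_peptide("TNF1"), -5.21,
                     tibble::tibble(position = 4L, residue = "S", ddg = -0.5),
                     coupling = tibble::tibble(pos_i = 4L, pos_j = 7L, epsilon = 0.3)),
    "nearest-neighbour"
  )
  expect_error(
    energy_landscape(lead_peptide("TNF1"), -5.21,
                     tibble::tibble(position = 18L, residue = "S", ddg = -0.5)),
    "randomized"
  )
})

test_that("true free energies are additive plus adjacent coupling", {
  ls0 <- tnf1_truth_landscape()
  expect_equal(true_dg(ls0, character(0)), -5.21)
  # non-adjacent pair: exact sum
  expect_equal(true_dg(ls0, c("M7K", "S11K")), -5.21 - 0.72 - 0.82)
  # adjacent pair with positive coupling: sum plus epsilon
  lsc <- tnf1_truth_landscape(
    coupling = tibble::tibble(pos_i = 4L, pos_j = 5L, epsilon = 0.3)
  )
  expect_equal(true_dg(lsc, c("D4S", "P5Y")), -5.21 - 0.77 - 0.58 + 0.3)
  # coupling requires both positions substituted
  expect_equal(true_dg(lsc, "D4S"), -5.21 - 0.77)
  expect_error(true_dg(ls0, "F1W"), "No landscape entry")
})

test_that("random landscapes are seed-reproducible with the stated structure", {
  a <- random_landscape(lead_peptide("TNF1"), n_enhancing = 5, seed = 9)
  b <- random_landscape(lead_peptide("TNF1"), n_enhancing = 5, seed = 9)
  expect_equal(a$contributions, b$contributions)
  expect_equal(sum(a$contributions$ddg < 0), 5L)
  expect_true(all(a$contributions$ddg[a$contributions$ddg < 0] >= -0.9))

  none <- random_landscape(lead_peptide("TNF1"), n_enhancing = 0, seed = 2)
  expect_true(all(none$contributions$ddg >= 0))

  expect_error(random_landscape(lead_peptide("TNF1"), n_enhancing = 1e6),
               "exceeds")

  # an enhancing set drawn near the measured gains puts the full combo in
  # the low-micromolar range
  best <- dplyr::slice_min(a$contributions, ddg, n = 4)
  best <- best[!duplicated(best$position), ]
  codes <- format_variant(best$position,
                          substring(a$lead$residues, best$position, best$position),
                          best$residue)
  kd_combo <- true_kd(a, codes)
  expect_lt(kd_combo, 20e-6)
  expect_gt(kd_combo, 0.1e-6)
})

test_that("screen responses follow the finite-time kinetic model", {
  ls0 <- tnf1_truth_landscape()
  lib <- enumerate_variants(ls0$lead, alphabet = c("S", "Y", "K"),
                            positions = c(4, 5, 7, 11))
  scr <- simulate_screen(ls0, lib, noise_sd = 0, seed = 1)
  # the 60 s window at kon_ref 1e4 is effectively equilibrated, so the
  # noiseless fold-change is the saturation-compressed equilibrium ratio
  lead_resp <- mean(scr$response[scr$is_lead])
  kd_lead <- true_kd(ls0, character(0))
  expect_equal(lead_resp,
               association_response(60, 50e-6, 1e4, 1e4 * kd_lead, 100),
               tolerance = 1e-9)

  # frozen example: lead Kd 160 uM, variant Kd 16 uM, screened at 50 uM
  ratio50 <- (50 / 66) / (50 / 210)
  expect_equal(ratio50, 3.18, tolerance = 1e-3)
  ratio5 <- (5 / 21) / (5 / 165)
  expect_equal(ratio5, 7.857, tolerance = 1e-3)
  expect_gt(ratio5, ratio50) # screening below Kd widens the dynamic range

  # monotonicity: screen fold-change increases with the true Ka ratio
  scr_map <- fold_change_map(scr)
  folds <- scr_map$cells
  kd_true <- vapply(folds$variant_code, function(cc) true_kd(ls0, cc), numeric(1))
  ord <- order(kd_true)
  expect_true(all(diff(folds$fold[ord]) <= 1e-9))

  # determinism under seed; different seeds differ
  scr_a <- simulate_screen(ls0, lib, noise_sd = 2, seed = 7)
  scr_b <- simulate_screen(ls0, lib, noise_sd = 2, seed = 7)
  scr_c <- simulate_screen(ls0, lib, noise_sd = 2, seed = 8)
  expect_equal(scr_a$response, scr_b$response)
  expect_false(identical(scr_a$response, scr_c$response))
})

test_that("modality simulators return the exact forward model at zero noise", {
  ls0 <- tnf1_truth_landscape()
  iso <- simulate_isotherm(ls0, "D4S", noise_sd = 0, replicates = 1)
  truth <- attr(iso, "truth")
  expect_equal(iso$response,
               equilibrium_response(iso$conc, truth$kd, truth$rmax))

  sg <- simulate_sensorgrams(ls0, "D4S", concs = 20e-6, noise_sd = 0)
  tr <- attr(sg, "truth")
  assoc <- sg[sg$phase == "assoc", ]
  expect_equal(assoc$response,
               association_response(assoc$time, 20e-6, tr$kon, tr$koff, tr$rmax))

  an <- simulate_anisotropy(ls0, "D4S", noise_sd = 0, replicates = 1)
  ta <- attr(an, "truth")
  expect_equal(
    an$signal,
    ta$s_free + (ta$s_bound - ta$s_free) *
      fraction_bound(an$protein_conc, ta$labeled_conc, ta$kd)
  )

  i1 <- simulate_isotherm(ls0, "D4S", seed = 4)
  i2 <- simulate_isotherm(ls0, "D4S", seed = 4)
  i3 <- simulate_isotherm(ls0, "D4S", seed = 5)
  expect_equal(i1$response, i2$response)
  expect_false(identical(i1$response, i3$response))
})

test_that("random lead libraries have the fixed linker and are seeded", {
  lib <- simulate_random_library(200, seed = 3)
  expect_equal(nrow(lib), 200L)
  expect_true(all(grepl("GSC$", lib$sequence)))
  expect_true(all(nchar(lib$sequence) == 20L))
  # 17 randomized positions vary across members
  prefix <- substr(lib$sequence, 1, 17)
  expect_gt(length(unique(prefix)), 190)
  expect_equal(simulate_random_library(10, seed = 3)$sequence,
               lib$sequence[1:10])
})
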