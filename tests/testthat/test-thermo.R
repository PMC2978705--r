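test_that("Kd <-> dG conversion is exact and round-trips", {
  expect_equal(kd_to_dg(1)$dg, 0)
  expect_equal(dg_to_kd(0)$kd, 1)
  expect_equal(kd_to_dg(160e-6)$dg, -5.178507, tolerance = 1e-6)
  expect_equal(dg_to_kd(-8.10)$kd, 1.16e-6, tolerance = 0.005)
  expect_equal(dg_to_kd(-5.93)$kd, 45e-6, tolerance = 0.005)

  # round trip across twelve decades
  kds <- 10^seq(-12, 0, by = 1)
  expect_equal(dg_to_kd(kd_to_dg(kds)$dg)$kd, kds, tolerance = 1e-12)

  expect_error(kd_to_dg(0), "positive")
  expect_error(kd_to_dg(-1e-6), "positive")
})

test_that("relative contributions reproduce the measured single-variant gains", {
  d4s <- relative_contribution(-5.98, -5.21, 0.04, 0.07)
  expect_equal(d4s$ddg, -0.77)
  expect_equal(round(d4s$ddg_se, 2), 0.08)

  p5y <- relative_contribution(-5.79, -5.21, 0.04, 0.07)
  expect_equal(p5y$ddg, -0.58)
  expect_equal(round(p5y$ddg_se, 2), 0.08)

  same <- relative_contribution(-5.21, -5.21)
  expect_equal(same$ddg, 0)
  expect_equal(same$ddg_se, 0)
})

test_that("additive combination reproduces the printed multi-variant predictions", {
  singles <- tnf1_point_variants()
  lead <- singles[singles$peptide == "TNF1", ]
  combos <- tnf1_combinations()
  for (i in seq_len(nrow(combos))) {
    pred <- combine_additive(lead$dg, lead$dg_se, table1_contribs(combos$codes[[i]]))
    if (combos$variant_set[i] == "D4Y+M7K") {
      # printed -6.66 differs by 0.01 from the sum of the printed inputs
      # (replicate averaging was done on unrounded internals)
      expect_equal(pred$dg_pred, -6.67)
      expect_equal(abs(pred$dg_pred - combos$dg_pred[i]), 0.01, tolerance = 1e-9)
    } else {
      expect_equal(pred$dg_pred, combos$dg_pred[i])
    }
    expect_equal(round(pred$se_pred, 2), combos$se_pred[i])
  }

  # headline quadruple and triple
  quad <- combine_additive(-5.21, 0.07, table1_contribs(c("D4S", "P5Y", "M7K", "S11K")))
  expect_equal(quad$dg_pred, -8.10)
  expect_equal(round(quad$se_pred, 2), 0.29)
  trip <- combine_additive(-5.21, 0.07, table1_contribs(c("D4S", "P5Y", "S11K")))
  expect_equal(trip$dg_pred, -7.38)

  # empty contribution list leaves the lead unchanged
  none <- combine_additive(-5.21, 0.07)
  expect_equal(none$dg_pred, -5.21)
  expect_equal(none$se_pred, 0.07)

  expect_error(
    combine_additive(-5.21, 0.07, table1_contribs(c("D4S", "D4Y"))),
    "same position"
  )
})

test_that("combination is permutation-invariant and quadrature-dominant", {
  contribs <- table1_contribs(c("D4S", "P5Y", "M7K", "S11K"))
  base <- combine_additive(-5.21, 0.07, contribs)
  set.seed(5)
  for (i in 1:5) {
    perm <- contribs[sample(nrow(contribs)), ]
    p <- combine_additive(-5.21, 0.07, perm)
    expect_equal(p$dg_pred, base$dg_pred)
    expect_equal(p$se_pred, base$se_pred)
  }
  expect_gte(base$se_pred, max(contribs$ddg_se))
})

test_that("predicted Kd ranges reproduce the printed micromolar endpoints", {
  quad <- combine_additive(-5.21, 0.07, table1_contribs(c("D4S", "P5Y", "M7K", "S11K")))
  rng <- predicted_kd_range(quad)
  expect_equal(signif(rng[["kd_high"]] * 1e6, 2), 1.9)
  expect_equal(signif(rng[["kd_low"]] * 1e6, 1), 0.7)

  trip <- combine_additive(-5.21, 0.07, table1_contribs(c("D4S", "P5Y", "S11K")))
  rng3 <- predicted_kd_range(trip)
  expect_equal(signif(rng3[["kd_high"]] * 1e6, 2), 5.3)
  expect_equal(signif(rng3[["kd_low"]] * 1e6, 2), 2.8)

  # zero error degenerates to the center
  exact <- combine_additive(-8.10, 0)
  expect_equal(predicted_kd_range(exact)[["kd_high"]], exact$kd_center)
  expect_equal(predicted_kd_range(exact)[["kd_low"]], exact$kd_center)
  expect_true(exact$kd_low <= exact$kd_center && exact$kd_center <= exact$kd_high)
})

test_that("fold-change is the Ka ratio with propagated error", {
  quad <- fold_change(160e-6, 1.6e-6, 19e-6, 0.3e-6)
  expect_equal(quad$fold, 100)
  expect_equal(round(quad$fold_se), 22)

  dbl <- fold_change(160e-6, 9.3e-6, 19e-6, 0.7e-6)
  expect_equal(signif(dbl$fold, 2), 17)

  expect_equal(fold_change(42e-6, 42e-6)$fold, 1)
})

test_that("kinetic Kd is koff/kon with propagated error", {
  tnf4opt <- kd_from_kinetics(5.8e4, 7.5e-3, 1.2e4, 0.8e-3)
  expect_equal(signif(tnf4opt$kd, 2), 1.3e-7)
  expect_equal(signif(tnf4opt$kd_se, 1), 3e-8)

  expect_equal(kd_from_kinetics(5, 5)$kd, 1)
  expect_equal(kd_from_kinetics(5.0e3, 1.6)$kd, 3.2e-4)
  expect_error(kd_from_kinetics(-1, 1), "positive")
})

test_that("quadrature propagation matches a Monte-Carlo oracle", {
  n <- 1e5
  withr::with_seed(101, {
    # fold-change: nonlinear ratio at ~12 and ~7.5 percent relative error
    # (the ratio distribution grows heavy-tailed beyond ~15 percent on the
    # denominator, where first-order propagation understates the SD)
    fc <- fold_change(160e-6, 9.3e-6, 19e-6, 0.7e-6)
    draws <- rnorm(n, 160e-6, 19e-6) / rnorm(n, 9.3e-6, 0.7e-6)
    expect_equal(sd(draws), fc$fold_se, tolerance = 0.05)

    # log transform
    dg <- kd_to_dg(160e-6, 19e-6)
    draws_dg <- rt_kcal() * log(rnorm(n, 160e-6, 19e-6))
    expect_equal(sd(draws_dg), dg$dg_se, tolerance = 0.05)

    # linear additive combination
    contribs <- table1_contribs(c("D4S", "P5Y", "M7K", "S11K"))
    pred <- combine_additive(-5.21, 0.07, contribs)
    draws_sum <- rnorm(n, -5.21, 0.07) +
      rowSums(sapply(seq_len(nrow(contribs)), function(i) {
        rnorm(n, contribs$ddg[i], contribs$ddg_se[i])
      }))
    expect_equal(sd(draws_sum), pred$se_pred, tolerance = 0.05)
  })
})
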