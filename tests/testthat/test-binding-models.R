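test_that("forward models agree with closed-form values and each other", {
  expect_equal(equilibrium_response(1e-6, 1e-6, 100), 50)
  expect_equal(equilibrium_response(3e-6, 1e-6, 100), 75)
  expect_equal(equilibrium_response(50e-6, 160e-6, 100), 100 * 50 / 210)

  expect_equal(association_response(0, 50e-6, 5e3, 1.6, 100), 0)
  # kobs at the lead's measured rates and screen concentration
  expect_equal(5e3 * 50e-6 + 1.6, 1.85)
  # long-time association equals the equilibrium response at kd = koff/kon
  expect_equal(
    association_response(1e4, 30e-6, 1e4, 0.5, 80),
    equilibrium_response(30e-6, 0.5 / 1e4, 80),
    tolerance = 1e-12
  )

  expect_equal(dissociation_response(0, 42, 0.2), 42)
  # half-life of the optimized triple variant's off-rate
  expect_equal(dissociation_response(log(2) / 7.5e-3, 1, 7.5e-3), 0.5)
  expect_equal(log(2) / 7.5e-3, 92.4, tolerance = 1e-3)
  t <- seq(0, 100, by = 1)
  expect_true(all(diff(dissociation_response(t, 10, 5)) <= 0))
})

test_that("fraction bound solves the 1:1 depletion equilibrium", {
  expect_equal(fraction_bound(0, 1e-7, 1e-6), 0)
  # dilute limit: half-saturation at P = kd
  expect_equal(fraction_bound(1e-6, 1e-12, 1e-6), 0.5, tolerance = 1e-5)
  expect_equal(fraction_bound(1.1e-6, 0.1e-6, 1.1e-6), 0.489, tolerance = 1e-3)

  # brute-force equilibrium solver oracle: find bound B with
  # (P-B)(L-B) = kd * B
  brute <- function(P, L, kd) {
    f <- function(B) (P - B) * (L - B) - kd * B
    uniroot(f, c(0, min(P, L)), tol = 1e-15)$root / L
  }
  set.seed(3)
  for (i in 1:20) {
    P <- 10^runif(1, -8, -4)
    L <- 10^runif(1, -9, -5)
    kd <- 10^runif(1, -8, -4)
    expect_equal(fraction_bound(P, L, kd), brute(P, L, kd), tolerance = 1e-6)
  }

  # in [0,1], monotone in P, converges to the dilute hyperbola as L -> 0
  P <- 10^seq(-9, -4, length.out = 30)
  f <- fraction_bound(P, 1e-7, 1.1e-6)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_equal(fraction_bound(P, 1e-15, 1.1e-6), P / (P + 1.1e-6), tolerance = 1e-6)
})

test_that("replicate aggregation is mean with standard error of the mean", {
  agg <- aggregate_replicates(c(1, 2, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(round(agg$se, 3), 0.577)

  single <- aggregate_replicates(5, ses = 0.4)
  expect_equal(single$mean, 5)
  expect_equal(single$se, 0.4)

  expect_equal(aggregate_replicates(c(2, 2, 2))$se, 0)
  expect_error(aggregate_replicates(numeric(0)), "No replicate")
})

test_that("equilibrium fit recovers truth on noiseless and noisy data", {
  concs <- 10^seq(-7.5, -4.5, length.out = 8)
  clean <- tibble::tibble(conc = concs,
                          response = equilibrium_response(concs, 1.6e-6, 100))
  fit <- fit_equilibrium(clean)
  expect_equal(fit$kd, 1.6e-6, tolerance = 1e-6)
  expect_equal(fit$rmax, 100, tolerance = 1e-6)
  expect_true(fit$converged)

  withr::with_seed(21, {
    noisy <- tidyr::expand_grid(conc = concs, replicate = 1:3)
    noisy$response <- equilibrium_response(noisy$conc, 1.6e-6, 100) + rnorm(nrow(noisy), sd = 2)
  })
  fitn <- fit_equilibrium(noisy)
  expect_lt(abs(fitn$kd - 1.6e-6), 3 * fitn$kd_se)

  # concentrations far below kd: noisy data give a wide relative SE and a
  # coverage warning (the curve carries almost no curvature information)
  low_concs <- c(1, 2, 4, 8, 16, 32) * 1e-9
  withr::with_seed(9, {
    low <- tibble::tibble(
      conc = low_concs,
      response = equilibrium_response(low_concs, 1.6e-6, 100) + rnorm(6, sd = 0.5)
    )
  })
  expect_warning(fit_low <- fit_equilibrium(low), "outside the concentration")
  expect_gt(fit_low$kd_se / fit_low$kd, 5 * fitn$kd_se / fitn$kd)

  expect_error(fit_equilibrium(tibble::tibble(conc = concs, response = 0)),
               "zero")
})

test_that("global kinetic fit recovers rate constants", {
  ls <- tnf1_truth_landscape()
  quad <- c("D4S", "P5Y", "M7K", "S11K")
  sg <- simulate_sensorgrams(ls, quad, concs = c(1e-6, 3e-6, 10e-6),
                             kon = 2.6e5, noise_sd = 0)
  truth <- attr(sg, "truth")
  fit <- fit_kinetics(sg)
  expect_equal(fit$kon, truth$kon, tolerance = 1e-4)
  expect_equal(fit$koff, truth$koff, tolerance = 1e-4)
  expect_equal(fit$kd, fit$koff / fit$kon)

  sgn <- simulate_sensorgrams(ls, quad, concs = c(1e-6, 3e-6, 10e-6),
                              kon = 2.6e5, noise_sd = 1, seed = 3)
  fitn <- fit_kinetics(sgn)
  expect_lt(abs(fitn$kon - truth$kon), 3 * fitn$kon_se)
  expect_lt(abs(fitn$koff - truth$koff), 3 * fitn$koff_se)

  expect_warning(
    fit_kinetics(dplyr::filter(sg, conc == 1e-6)),
    "single concentration"
  )
})

test_that("anisotropy fit recovers Kd, and depletion matches the dilute model when L << Kd", {
  ls <- tnf1_truth_landscape()
  quad <- c("D4S", "P5Y", "M7K", "S11K")
  an <- simulate_anisotropy(ls, quad, noise_sd = 0, replicates = 1)
  truth <- attr(an, "truth")
  fit <- fit_anisotropy(an, labeled_conc = truth$labeled_conc)
  expect_equal(fit$kd, truth$kd, tolerance = 1e-5)

  # L = kd/10: depletion and dilute fits agree within 2 percent
  kd <- 1e-6; L <- 1e-7
  P <- 10^seq(-8, -4.5, length.out = 12)
  sig <- 0.05 + 0.2 * fraction_bound(P, L, kd)
  d <- tibble::tibble(protein_conc = P, signal = sig)
  fit_dep <- fit_anisotropy(d, labeled_conc = L)
  fit_dil <- fit_anisotropy(d, labeled_conc = 1e-15)
  expect_equal(fit_dil$kd, fit_dep$kd, tolerance = 0.06)

  expect_error(
    fit_anisotropy(tibble::tibble(protein_conc = P, signal = rep(0.1, length(P))),
                   labeled_conc = L),
    "constant"
  )
})

test_that("fitted 2-SE intervals achieve near-nominal coverage", {
  # empirical coverage over seeded noisy simulations; >= 90 percent
  ls <- tnf1_truth_landscape()
  kd_true <- true_kd(ls, "D4S")

  hits_eq <- vapply(1:200, function(s) {
    iso <- simulate_isotherm(ls, "D4S",
                             concs = 10^seq(-6.5, -3.5, length.out = 6),
                             noise_sd = 2, replicates = 2, seed = s)
    f <- suppressWarnings(fit_equilibrium(iso))
    abs(f$kd - kd_true) <= 2 * f$kd_se
  }, logical(1))
  expect_gte(mean(hits_eq), 0.9)

  hits_an <- vapply(1:200, function(s) {
    an <- simulate_anisotropy(ls, "D4S",
                              protein_concs = 10^seq(-7, -3, length.out = 8),
                              noise_sd = 0.004, replicates = 2, seed = s)
    f <- suppressWarnings(fit_anisotropy(an, labeled_conc = 100e-9))
    abs(f$kd - kd_true) <= 2 * f$kd_se
  }, logical(1))
  expect_gte(mean(hits_an), 0.9)

  kd_quad <- true_kd(ls, c("D4S", "P5Y", "M7K", "S11K"))
  hits_kin <- vapply(1:60, function(s) {
    sg <- simulate_sensorgrams(ls, c("D4S", "P5Y", "M7K", "S11K"),
                               concs = c(1e-6, 10e-6), kon = 2.6e5,
                               dt = 2, noise_sd = 1, seed = s)
    f <- suppressWarnings(fit_kinetics(sg))
    kd_hat <- f$koff / f$kon
    abs(kd_hat - kd_quad) <= 2 * f$kd_se
  }, logical(1))
  expect_gte(mean(hits_kin), 0.9)
})
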