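# Forward models for the three measurement modalities: SPR equilibrium
# isotherms, SPR 1:1 Langmuir kinetics, and fluorescence-anisotropy
# titration with ligand depletion. Plain 1:1 binding throughout; no
# mass-transport or bivalent-analyte terms.

#' Equilibrium SPR response of a 1:1 interaction
#'
#' The Langmuir isotherm `R = Rmax C / (C + Kd)`.
#'
#' @param conc Analyte concentration(s), molar.
#' @param kd Dissociation constant, molar.
#' @param rmax Saturating response, RU (1 for Rmax-normalized data).
#' @return Response in the units of `rmax`.
#' @examples
#' equilibrium_response(50e-6, 160e-6, 100) # 23.8 RU
#' @export
equilibrium_response <- function(conc, kd, rmax) {
  if (any(conc < 0)) abort("`conc` must be non-negative.")
  stopifnot_scalar_number(kd, "kd", positive = TRUE)
  rmax * conc / (conc + kd)
}

#' Association-phase response of the 1:1 kinetic model
#'
#' `R(t) = Req (1 - exp(-kobs t))` with `kobs = kon C + koff` and
#' `Req = Rmax C kon / (C kon + koff)`.
#'
#' @param t Time(s) since injection start, seconds.
#' @param conc Analyte concentration, molar.
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param rmax Saturating response, RU.
#' @return Response in RU.
#' @export
association_response <- function(t, conc, kon, koff, rmax) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  kobs <- kon * conc + koff
  req <- rmax * conc * kon / kobs
  req * (1 - exp(-kobs * t))
}

#' Dissociation-phase response of the 1:1 kinetic model
#'
#' Exponential decay `R(t) = R0 exp(-koff t)` from the response at the end
#' of association.
#'
#' @param t Time(s) since the start of dissociation, seconds.
#' @param r0 Response at the association/dissociation boundary, RU.
#' @param koff Dissociation rate constant, 1/s.
#' @return Response in RU.
#' @export
dissociation_response <- function(t, r0, koff) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (any(r0 < 0)) abort("`r0` must be non-negative.")
  r0 * exp(-koff * t)
}

#' Fraction of labeled ligand bound, with depletion
#'
#' Exact 1:1 solution of the equilibrium when the labeled species L is not
#' negligible relative to Kd: the usual quadratic, written in the
#' numerically stable conjugate form
#' `f = 2P / (a + sqrt(a^2 - 4 P L))`, `a = P + L + Kd`,
#' which passes smoothly to the dilute hyperbola `P/(P + Kd)` as L -> 0.
#'
#' @param protein_conc Titrant (protein) concentration(s) P, molar.
#' @param labeled_conc Fixed labeled-peptide concentration L, molar.
#' @param kd Dissociation constant, molar.
#' @return Fraction bound in \[0, 1\].
#' @examples
#' fraction_bound(1.1e-6, 0.1e-6, 1.1e-6) # 0.489
#' @export
fraction_bound <- function(protein_conc, labeled_conc, kd) {
  if (any(protein_conc < 0) || any(labeled_conc < 0)) {
    abort("Concentrations must be non-negative.")
  }
  stopifnot_scalar_number(kd, "kd", positive = TRUE)
  a <- protein_conc + labeled_conc + kd
  disc <- pmax(a^2 - 4 * protein_conc * labeled_conc, 0)
  2 * protein_conc / (a + sqrt(disc))
}

#' Aggregate replicate estimates
#'
#' Replicate affinity or free-energy estimates are summarized as an
#' unweighted mean with the standard error of the mean (sample SD over
#' sqrt(n)). A single estimate passes through with its own fit standard
#' error. Means of Kd and of dG are taken separately by callers — the mean
#' of one is deliberately never recomputed from the mean of the other.
#'
#' @param values Numeric vector of replicate estimates.
#' @param ses Optional per-replicate standard errors (used only when
#'   `length(values) == 1`).
#' @return Tibble with columns `mean`, `se`, `n`.
#' @examples
#' aggregate_replicates(c(1, 2, 3)) # 2 +/- 0.577
#' @export
aggregate_replicates <- function(values, ses = NULL) {
  if (length(values) == 0L) abort("No replicate estimates to aggregate.")
  n <- length(values)
  se <- if (n > 1L) sd(values) / sqrt(n) else (ses[1] %||% 0)
  tibble::tibble(mean = mean(values), se = se, n = n)
}
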