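# The additivity engine: Kd <-> standard binding free energy, relative
# contributions, additive combination with quadrature error propagation.
# Internal units are molar for Kd and kcal/mol for energies; micromolar and
# nanomolar appear only at I/O.

#' Gas constant in kcal/(mol K)
#' @export
gas_constant_kcal <- 1.9872e-3

#' Thermal energy RT in kcal/mol
#' @param temperature Temperature in kelvin (default 298.15).
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(temperature = 298.15) {
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  gas_constant_kcal * temperature
}

#' Convert a dissociation constant to a standard binding free energy
#'
#' `dG = RT ln(Kd)` with Kd in molar, so tighter binding is more negative.
#' The standard error maps by first-order propagation,
#' `se(dG) = RT se(Kd)/Kd`.
#'
#' @param kd Dissociation constant(s), molar; must be positive.
#' @param kd_se Standard error(s) on Kd, molar (default 0).
#' @param temperature Kelvin (default 298.15).
#' @return Tibble with columns `dg` and `dg_se` (kcal/mol).
#' @examples
#' kd_to_dg(160e-6, 19e-6)
#' @export
kd_to_dg <- function(kd, kd_se = 0, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) abort("`kd` must be positive and finite.")
  if (any(kd_se < 0)) abort("`kd_se` must be non-negative.")
  rt <- rt_kcal(temperature)
  tibble::tibble(dg = rt * log(kd), dg_se = rt * kd_se / kd)
}

#' Convert a standard binding free energy to a dissociation constant
#'
#' Inverse of [kd_to_dg()]: `Kd = exp(dG/RT)`, with
#' `se(Kd) = Kd se(dG)/RT`.
#'
#' @param dg Free energy(ies), kcal/mol.
#' @param dg_se Standard error(s), kcal/mol (default 0).
#' @param temperature Kelvin (default 298.15).
#' @return Tibble with columns `kd` and `kd_se` (molar).
#' @examples
#' dg_to_kd(-8.10)
#' @export
dg_to_kd <- function(dg, dg_se = 0, temperature = 298.15) {
  if (any(dg_se < 0)) abort("`dg_se` must be non-negative.")
  rt <- rt_kcal(temperature)
  kd <- exp(dg / rt)
  tibble::tibble(kd = kd, kd_se = kd * dg_se / rt)
}

#' Relative free-energy contribution of a point variant
#'
#' The quantity assumed additive: the difference between a variant's
#' standard binding free energy and the lead's, with the two standard
#' errors combined in quadrature.
#'
#' @param variant_dg,lead_dg Free energies, kcal/mol (vectorized over
#'   variants).
#' @param variant_se,lead_se Standard errors, kcal/mol.
#' @return Tibble with columns `ddg` and `ddg_se`.
#' @examples
#' relative_contribution(-5.98, -5.21, 0.04, 0.07) # -0.77 +/- 0.08
#' @export
relative_contribution <- function(variant_dg, lead_dg, variant_se = 0, lead_se = 0) {
  if (any(!is.finite(variant_dg)) || any(!is.finite(lead_dg))) {
    abort("Free energies must be finite.")
  }
  tibble::tibble(
    ddg = variant_dg - lead_dg,
    ddg_se = sqrt(variant_se^2 + lead_se^2)
  )
}

#' Combine point-variant contributions additively
#'
#' The additive prediction for a multi-variant: the lead free energy plus
#' the sum of the component relative contributions, with the standard error
#' propagated as the root-sum-square of all input errors. The predicted Kd
#' range follows by converting `dg_pred +/- se_pred` (the unrounded error)
#' at the working temperature; the weak-binding end of the range comes from
#' the less negative bound.
#'
#' @param lead_dg Lead standard binding free energy, kcal/mol.
#' @param lead_se Its standard error.
#' @param contributions Tibble with columns `ddg`, `ddg_se` and optionally
#'   `variant_code` and `position` (positions, when present, must be
#'   distinct).
#' @param temperature Kelvin (default 298.15).
#' @return An `additive_prediction` object with fields `dg_pred`, `se_pred`,
#'   `kd_center`, `kd_high`, `kd_low` (molar) and the contribution table.
#' @examples
#' contribs <- tibble::tibble(
#'   variant_code = c("D4S", "P5Y", "M7K", "S11K"),
#'   ddg = c(-0.77, -0.58, -0.72, -0.82),
#'   ddg_se = c(0.08, 0.08, 0.22, 0.13)
#' )
#' combine_additive(-5.21, 0.07, contribs)
#' @export
combine_additive <- function(lead_dg, lead_se = 0, contributions = NULL,
                             temperature = 298.15) {
  stopifnot_scalar_number(lead_dg, "lead_dg")
  stopifnot_scalar_number(lead_se, "lead_se")
  if (lead_se < 0) abort("`lead_se` must be non-negative.")
  if (is.null(contributions)) {
    contributions <- tibble::tibble(ddg = numeric(0), ddg_se = numeric(0))
  }
  contributions <- tibble::as_tibble(contributions)
  if (!all(c("ddg", "ddg_se") %in% names(contributions))) {
    abort("`contributions` needs columns `ddg` and `ddg_se`.")
  }
  if ("position" %in% names(contributions) && anyDuplicated(contributions$position)) {
    abort("Two contributions at the same position cannot be combined.")
  }
  dg_pred <- lead_dg + sum(contributions$ddg)
  se_pred <- sqrt(lead_se^2 + sum(contributions$ddg_se^2))
  rt <- rt_kcal(temperature)
  structure(
    list(
      dg_pred = dg_pred,
      se_pred = se_pred,
      kd_center = exp(dg_pred / rt),
      kd_high = exp((dg_pred + se_pred) / rt),
      kd_low = exp((dg_pred - se_pred) / rt),
      contributions = contributions,
      lead_dg = lead_dg,
      lead_se = lead_se,
      temperature = temperature
    ),
    class = "additive_prediction"
  )
}

#' @export
print.additive_prediction <- function(x, ...) {
  codes <- x$contributions$variant_code %||% NULL
  label <- if (!is.null(codes) && length(codes)) paste(codes, collapse = "+") else "(no variants)"
  cat(sprintf(
    "Additive prediction for %s\n  dG = %.2f +/- %.2f kcal/mol\n  Kd range %s - %s (center %s)\n",
    label, x$dg_pred, x$se_pred,
    format_kd(x$kd_high), format_kd(x$kd_low), format_kd(x$kd_center)
  ))
  invisible(x)
}

#' @export
#' @method tidy additive_prediction
tidy.additive_prediction <- function(x, ...) {
  codes <- x$contributions$variant_code %||% character(0)
  tibble::tibble(
    variant_set = paste(codes, collapse = "+"),
    dg_pred = x$dg_pred,
    se_pred = x$se_pred,
    kd_center = x$kd_center,
    kd_high = x$kd_high,
    kd_low = x$kd_low
  )
}

#' Predicted Kd range of an additive prediction
#'
#' Evaluates `Kd = exp((dG +/- se)/RT)`; the high (weak-binding) end comes
#' from the less negative bound. Reported high-to-low, matching the
#' convention of affinity tables.
#'
#' @param prediction An [combine_additive()] result.
#' @return Named numeric vector `c(kd_high, kd_low)` in molar.
#' @export
predicted_kd_range <- function(prediction) {
  stopifnot(inherits(prediction, "additive_prediction"))
  c(kd_high = prediction$kd_high, kd_low = prediction$kd_low)
}

#' Fold-change in affinity relative to a lead
#'
#' The ratio of association constants, `Ka(variant)/Ka(lead) =
#' Kd(lead)/Kd(variant)`, with the standard error from first-order
#' propagation of both relative errors.
#'
#' @param kd_lead,kd_variant Dissociation constants, molar (vectorized over
#'   variants).
#' @param lead_se,variant_se Standard errors, molar.
#' @return Tibble with columns `fold` and `fold_se`.
#' @examples
#' fold_change(160e-6, 1.6e-6, 19e-6, 0.3e-6) # 100 +/- 22
#' @export
fold_change <- function(kd_lead, kd_variant, lead_se = 0, variant_se = 0) {
  if (any(kd_lead <= 0) || any(kd_variant <= 0)) abort("Dissociation constants must be positive.")
  fold <- kd_lead / kd_variant
  tibble::tibble(
    fold = fold,
    fold_se = fold * sqrt((lead_se / kd_lead)^2 + (variant_se / kd_variant)^2)
  )
}

#' Dissociation constant from 1:1 kinetic rate constants
#'
#' `Kd = koff/kon`, with the standard error from first-order propagation of
#' the rate-constant errors.
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param kon_se,koff_se Standard errors.
#' @return Tibble with columns `kd` and `kd_se` (molar).
#' @examples
#' kd_from_kinetics(5.8e4, 7.5e-3, 1.2e4, 0.8e-3) # 130 +/- 30 nM
#' @export
kd_from_kinetics <- function(kon, koff, kon_se = 0, koff_se = 0) {
  if (any(kon <= 0) || any(koff <= 0)) abort("Rate constants must be positive.")
  kd <- koff / kon
  tibble::tibble(
    kd = kd,
    kd_se = kd * sqrt((koff_se / koff)^2 + (kon_se / kon)^2)
  )
}
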