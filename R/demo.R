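#' Recompute the multi-variant additivity arithmetic from packaged values
#'
#' Rebuilds, from the packaged single-variant measurements
#' ([tnf1_point_variants()]), the additive predictions for the seven TNF1
#' multi-variants: predicted dG as lead plus the sum of the component
#' contributions, predicted sigma by quadrature, and the Kd range from
#' `exp((dG +/- sigma)/RT)` at 298.15 K — alongside the observed values and
#' Ka-ratio fold-changes, and both observed-vs-predicted slope estimators.
#'
#' @param temperature Kelvin (default 298.15).
#' @return List with `predictions` (tibble: one row per variant set, with
#'   `dg_pred`, `se_pred`, `kd_high_um`, `kd_low_um`, `fold_change`,
#'   observed columns) and `additivity` (an [assess_additivity()] report).
#' @examples
#' run_demo()$predictions
#' @export
run_demo <- function(temperature = 298.15) {
  singles <- tnf1_point_variants()
  lead <- singles[singles$peptide == "TNF1", ]
  combos <- tnf1_combinations()
  pred <- purrr::map(combos$codes, function(codes) {
    combine_additive(
      lead$dg, lead$dg_se,
      singles[match(codes, singles$peptide),
              c("peptide", "position", "ddg", "ddg_se")] |>
        dplyr::rename(variant_code = "peptide"),
      temperature = temperature
    )
  })
  fc <- fold_change(lead$kd, combos$kd_obs, lead$kd_se, combos$kd_obs_se)
  predictions <- tibble::tibble(
    variant_set = combos$variant_set,
    dg_pred = vapply(pred, function(p) p$dg_pred, numeric(1)),
    se_pred = vapply(pred, function(p) p$se_pred, numeric(1)),
    kd_high_um = vapply(pred, function(p) signif(p$kd_high * 1e6, 2), numeric(1)),
    kd_low_um = vapply(pred, function(p) signif(p$kd_low * 1e6, 2), numeric(1)),
    dg_obs = combos$dg_obs,
    se_obs = combos$se_obs,
    kd_obs_um = combos$kd_obs * 1e6,
    fold_change = fc$fold,
    fold_change_se = fc$fold_se
  )
  additivity <- assess_additivity(
    tibble::tibble(
      variant_set = predictions$variant_set,
      dg_obs = predictions$dg_obs,
      se_obs = predictions$se_obs,
      dg_pred = predictions$dg_pred,
      se_pred = predictions$se_pred
    )
  )
  list(predictions = predictions, additivity = additivity)
}
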