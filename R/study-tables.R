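# Packaged reference measurements from the TNF-alpha / transferrin peptide
# optimization study. These are the printed single- and multi-variant
# affinities the additivity arithmetic is demonstrated on; energies in
# kcal/mol, dissociation constants in molar.

#' Measured TNF1 lead and point-variant affinities
#'
#' Equilibrium SPR measurements for the TNF1 lead and its five selected
#' enhancing point-variants. dG and Kd were averaged separately over
#' replicates (so the printed pairs are not exact transforms of one
#' another); `ddg` is the relative contribution, variant minus lead.
#'
#' @return Tibble with columns `peptide`, `dg`, `dg_se` (kcal/mol), `kd`,
#'   `kd_se` (molar), `fold`, `fold_se`, `ddg`, `ddg_se`, and `position`,
#'   `wild`, `sub` for the variants.
#' @export
tnf1_point_variants <- function() {
  tbl <- tibble::tibble(
    peptide = c("TNF1", "D4S", "D4Y", "P5Y", "M7K", "S11K"),
    dg      = c(-5.21, -5.98, -5.95, -5.79, -5.93, -6.03),
    dg_se   = c( 0.07,  0.04,  0.06,  0.04,  0.20,  0.10),
    kd      = c(160, 42, 44, 58, 57, 40) * 1e-6,
    kd_se   = c(19, 2.4, 4.8, 3.4, 20, 7.2) * 1e-6,
    fold    = c(NA, 3.8, 3.6, 2.7, 2.8, 3.9),
    fold_se = c(NA, 0.5, 0.6, 0.4, 1.0, 0.9),
    ddg     = c(NA, -0.77, -0.74, -0.58, -0.72, -0.82),
    ddg_se  = c(NA,  0.08,  0.10,  0.08,  0.22,  0.13)
  )
  v <- suppressWarnings(parse_variants(tbl$peptide[-1], lead_peptide("TNF1")))
  tbl$position <- c(NA_integer_, v$position)
  tbl$wild <- c(NA_character_, v$wild)
  tbl$sub <- c(NA_character_, v$sub)
  tbl
}

#' Measured and predicted TNF1 multi-variant affinities
#'
#' The four double, two triple and one quadruple TNF1 variants: observed
#' equilibrium affinities alongside the additive predictions as printed
#' (`dg_pred`, `se_pred`, and the Kd range endpoints in micromolar). Note
#' the printed D4Y+M7K prediction (-6.66) differs by 0.01 kcal/mol from the
#' direct sum of the printed single-variant inputs (-6.67); replicate
#' averaging was done on unrounded internals.
#'
#' @return Tibble with columns `variant_set`, `codes` (list of variant
#'   codes), `dg_obs`, `se_obs`, `kd_obs`, `kd_obs_se` (molar), `fold_obs`,
#'   `fold_obs_se`, `dg_pred`, `se_pred`, `kd_range_high_um`,
#'   `kd_range_low_um`.
#' @export
tnf1_combinations <- function() {
  tibble::tibble(
    variant_set = c("D4Y+M7K", "D4Y+S11K", "P5Y+M7K", "P5Y+S11K",
                    "D4S+P5Y+M7K", "D4S+P5Y+S11K", "D4S+P5Y+M7K+S11K"),
    codes = list(
      c("D4Y", "M7K"), c("D4Y", "S11K"), c("P5Y", "M7K"), c("P5Y", "S11K"),
      c("D4S", "P5Y", "M7K"), c("D4S", "P5Y", "S11K"),
      c("D4S", "P5Y", "M7K", "S11K")
    ),
    dg_obs  = c(-6.54, -6.87, -6.24, -6.31, -6.63, -7.03, -7.97),
    se_obs  = c( 0.07,  0.05,  0.04,  0.04,  0.04,  0.04,  0.11),
    kd_obs  = c(17, 9.3, 27, 24, 14, 7.0, 1.6) * 1e-6,
    kd_obs_se = c(1.9, 0.7, 1.8, 1.4, 1.0, 0.5, 0.3) * 1e-6,
    fold_obs = c(9.4, 17, 5.8, 6.6, 11, 23, 100),
    fold_obs_se = c(1.6, 2.5, 0.8, 0.9, 1.6, 3.2, 22),
    dg_pred = c(-6.66, -6.77, -6.51, -6.61, -7.28, -7.38, -8.10),
    se_pred = c( 0.25,  0.18,  0.24,  0.17,  0.26,  0.19,  0.29),
    kd_range_high_um = c(20, 15, 25, 19, 7.0, 5.3, 1.9),
    kd_range_low_um  = c(8.5, 8.0, 11, 11, 3.0, 2.8, 0.7)
  )
}

#' Kinetic rate constants for the TNF-alpha peptides
#'
#' 1:1 kinetic fit results for the TNF1 lead, its optimized quadruple
#' variant (TNF1-opt = D4S+P5Y+M7K+S11K) and the optimized TNF4 triple
#' variant (TNF4-opt = Y1W+D5Y+T10Y).
#'
#' @return Tibble with columns `peptide`, `kon`, `kon_se` (1/(M s)),
#'   `koff`, `koff_se` (1/s).
#' @export
tnf_kinetics <- function() {
  tibble::tibble(
    peptide = c("TNF1", "TNF1-opt", "TNF4-opt"),
    kon     = c(5.0e3, 2.6e5, 5.8e4),
    kon_se  = c(1.7e3, 0.2e5, 1.2e4),
    koff    = c(1.6, 0.2, 7.5e-3),
    koff_se = c(0.5, 0.02, 0.8e-3)
  )
}

#' Measured TRF26 (transferrin-binding) lead and variant affinities
#'
#' The second-target demonstration: the TRF26 lead, its two selected
#' point-variants from a 323-member scan, and the observed double variant.
#'
#' @return Tibble with columns `peptide`, `kd`, `kd_se` (molar).
#' @export
trf26_variants <- function() {
  tibble::tibble(
    peptide = c("TRF26", "P6Y", "H12F", "P6Y+H12F"),
    kd = c(85e-6, 8.6e-6, 9.7e-6, 0.5e-6),
    kd_se = c(14e-6, 1.6e-6, 1.6e-6, 0.1e-6)
  )
}
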