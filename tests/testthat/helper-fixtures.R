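# Shared fixtures: a landscape whose contribution table reproduces the
# measured TNF1 single-variant gains, and a compact test configuration for
# end-to-end runs (small alphabet, reduced grids) so simulations stay fast.

tnf1_truth_landscape <- function(coupling = NULL) {
  lead <- lead_peptide("TNF1")
  # complete table over the Y/S/K test alphabet: mildly detrimental
  # background, with the five measured enhancing cells overridden
  cells <- enumerate_variants(lead, alphabet = c("Y", "S", "K"))
  tab <- tibble::tibble(position = cells$position, residue = cells$sub,
                        ddg = 0.2)
  focal <- tibble::tibble(
    position = c(4L, 4L, 5L, 7L, 11L),
    residue  = c("S", "Y", "Y", "K", "K"),
    ddg      = c(-0.77, -0.74, -0.58, -0.72, -0.82)
  )
  idx <- match(paste(focal$position, focal$residue),
               paste(tab$position, tab$residue))
  tab$ddg[idx] <- focal$ddg
  energy_landscape(lead, -5.21, contributions = tab, coupling = coupling)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(
      alphabet = c("Y", "S", "K"),
      screen_conc = 10e-6,
      screen_noise_sd = 0.5,
      fold_threshold = 1.5,
      isotherm_concs = 10^seq(-6.5, -3.5, length.out = 6),
      isotherm_replicates = 2,
      isotherm_noise_sd = 0.5,
      n_fits = 3
    ),
    list(...)
  )
  do.call(optimization_config, args)
}

table1_contribs <- function(codes) {
  singles <- tnf1_point_variants()
  rows <- singles[match(codes, singles$peptide), ]
  tibble::tibble(
    variant_code = rows$peptide,
    position = rows$position,
    ddg = rows$ddg,
    ddg_se = rows$ddg_se
  )
}
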