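# Simulated binding assays driven by a ground-truth landscape. All
# randomness flows from one explicit seed per call; independent artifacts
# derive sub-seeds with derive_seed() so outputs are reproducible
# stream-by-stream. Noise is i.i.d. Gaussian on the response scale.

#' Simulate an SPR point-variant screen
#'
#' Each library member (and the lead, flagged `is_lead`) is injected at one
#' fixed concentration and its response read at the end of a finite
#' association window. Responses are simulated mechanistically through the
#' 1:1 kinetic model rather than as equilibrium values, because a
#' 60-second association with a slow on-rate need not equilibrate: the
#' reference on-rate is shared across variants (`kon_ref`) and each
#' variant's off-rate follows from its true Kd, `koff = kon_ref * Kd`.
#' Because RU reflects bound mass, each clean response is scaled by the
#' variant's molecular weight relative to the lead's; the
#' molecular-weight adjustment in [fold_change_map()] undoes exactly this.
#'
#' @param landscape An [energy_landscape()].
#' @param library A variant library from [enumerate_variants()] on the same
#'   lead.
#' @param conc Fixed screen concentration, molar (default 50e-6: roughly
#'   3-fold below a high-micromolar lead Kd, which stretches the high end
#'   of the fold-change dynamic range).
#' @param assoc_time Association window, seconds (default 60).
#' @param replicates Replicate injections per peptide (default 3).
#' @param rmax Saturating response, RU (default 100).
#' @param noise_sd Gaussian response noise SD, RU (default 2).
#' @param kon_ref Reference association rate constant, 1/(M s) (default 1e4).
#' @param seed Integer seed.
#' @return Tibble with columns `variant_code`, `sequence`, `position`,
#'   `wild`, `sub`, `mw_da`, `is_lead`, `replicate`, `response`, `conc`.
#' @export
simulate_screen <- function(landscape, library,
                            conc = 50e-6, assoc_time = 60,
                            replicates = 3, rmax = 100,
                            noise_sd = 2, kon_ref = 1e4, seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (!identical(library$variant_code, unique(library$variant_code))) {
    abort("Library variant codes must be unique.")
  }
  stopifnot_scalar_number(conc, "conc", positive = TRUE)
  if (replicates < 1L) abort("`replicates` must be >= 1.")
  lead <- landscape$lead
  members <- tibble::tibble(
    variant_code = c(lead$name, library$variant_code),
    sequence = c(lead$residues, library$sequence),
    position = c(NA_integer_, library$position),
    wild = c(NA_character_, library$wild),
    sub = c(NA_character_, library$sub),
    is_lead = c(TRUE, rep(FALSE, nrow(library)))
  )
  members$mw_da <- molecular_weight(members$sequence)
  members$kd_true <- vapply(seq_len(nrow(members)), function(i) {
    if (members$is_lead[i]) true_kd(landscape, character(0))
    else true_kd(landscape, members$variant_code[i])
  }, numeric(1))
  # RU scales with bound mass: occupancy kinetics times the analyte's mass
  # relative to the lead (whose saturating response is `rmax`)
  clean <- association_response(assoc_time, conc, kon_ref,
                                kon_ref * members$kd_true, rmax) *
    members$mw_da / members$mw_da[[1]]
  out <- tidyr::expand_grid(
    dplyr::select(members, -"kd_true"),
    replicate = seq_len(replicates)
  )
  out$conc <- conc
  withr::with_seed(derive_seed(seed, 1L), {
    out$response <- rep(clean, each = replicates) +
      rnorm(nrow(out), sd = noise_sd)
  })
  out
}

#' Simulate an equilibrium binding isotherm
#'
#' Forward Langmuir responses for one variant set on a concentration grid,
#' plus seeded Gaussian noise. The true Kd and Rmax are attached as
#' attributes `truth` for recovery tests.
#'
#' @param landscape An [energy_landscape()].
#' @param codes Variant codes defining the peptide (empty = lead).
#' @param concs Concentration grid, molar.
#' @param rmax Saturating response, RU.
#' @param noise_sd Gaussian noise SD, RU.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble with columns `conc`, `response`, `replicate`.
#' @export
simulate_isotherm <- function(landscape, codes = character(0),
                              concs = 10^seq(-6.5, -3.5, length.out = 8),
                              rmax = 100, noise_sd = 2, replicates = 3,
                              seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(concs) == 0L) abort("Concentration grid must be non-empty.")
  kd <- true_kd(landscape, codes)
  out <- tidyr::expand_grid(conc = concs, replicate = seq_len(replicates))
  clean <- equilibrium_response(out$conc, kd, rmax)
  withr::with_seed(derive_seed(seed, 2L), {
    out$response <- clean + rnorm(nrow(out), sd = noise_sd)
  })
  attr(out, "truth") <- list(kd = kd, rmax = rmax, codes = codes, seed = seed)
  out
}

#' Simulate SPR sensorgrams
#'
#' Association/dissociation traces from the 1:1 kinetic model for one
#' variant set, across several concentrations, with seeded Gaussian noise.
#' The off-rate follows from the landscape's true Kd and `kon`.
#'
#' @inheritParams simulate_isotherm
#' @param concs Analyte concentrations, molar.
#' @param kon True association rate constant, 1/(M s).
#' @param assoc_time,dissoc_time Phase lengths, seconds.
#' @param dt Sampling interval, seconds.
#' @return Tibble with columns `time` (within-phase), `response`, `conc`,
#'   `phase`; truth in `attr(, "truth")`.
#' @export
simulate_sensorgrams <- function(landscape, codes = character(0),
                                 concs = c(10e-6, 30e-6, 100e-6),
                                 kon = 1e4,
                                 assoc_time = 60, dissoc_time = 60, dt = 1,
                                 rmax = 100, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(concs) == 0L) abort("Concentration grid must be non-empty.")
  kd <- true_kd(landscape, codes)
  koff <- kon * kd
  one <- function(cc) {
    ta <- seq(0, assoc_time, by = dt)
    td <- seq(dt, dissoc_time, by = dt)
    r_end <- association_response(assoc_time, cc, kon, koff, rmax)
    dplyr::bind_rows(
      tibble::tibble(time = ta, response = association_response(ta, cc, kon, koff, rmax),
                     conc = cc, phase = "assoc"),
      tibble::tibble(time = td, response = dissociation_response(td, r_end, koff),
                     conc = cc, phase = "dissoc")
    )
  }
  out <- dplyr::bind_rows(purrr::map(concs, one))
  withr::with_seed(derive_seed(seed, 3L), {
    out$response <- out$response + rnorm(nrow(out), sd = noise_sd)
  })
  attr(out, "truth") <- list(kd = kd, kon = kon, koff = koff, rmax = rmax,
                             codes = codes, seed = seed)
  out
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Signal = `s_free + (s_bound - s_free) * fraction_bound` at a fixed
#' labeled-peptide concentration, with seeded Gaussian noise.
#'
#' @inheritParams simulate_isotherm
#' @param protein_concs Titrant concentrations, molar.
#' @param labeled_conc Fixed labeled-peptide concentration, molar (default
#'   100e-9).
#' @param s_free,s_bound Free and bound endpoint signals.
#' @return Tibble with columns `protein_conc`, `signal`, `replicate`;
#'   truth in `attr(, "truth")`.
#' @export
simulate_anisotropy <- function(landscape, codes = character(0),
                                protein_concs = 10^seq(-8, -4.5, length.out = 10),
                                labeled_conc = 100e-9,
                                s_free = 0.05, s_bound = 0.25,
                                noise_sd = 0.002, replicates = 3, seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(protein_concs) == 0L) abort("Titration grid must be non-empty.")
  kd <- true_kd(landscape, codes)
  out <- tidyr::expand_grid(protein_conc = protein_concs,
                            replicate = seq_len(replicates))
  f <- fraction_bound(out$protein_conc, labeled_conc, kd)
  withr::with_seed(derive_seed(seed, 4L), {
    out$signal <- s_free + (s_bound - s_free) * f + rnorm(nrow(out), sd = noise_sd)
  })
  attr(out, "truth") <- list(kd = kd, labeled_conc = labeled_conc,
                             s_free = s_free, s_bound = s_bound,
                             codes = codes, seed = seed)
  out
}

#' Simulate a sparse random peptide library
#'
#' Uniform draws over the 20-letter alphabet at the randomized positions,
#' with the fixed C-terminal linker appended — the kind of sparse random
#' 20-mer library leads are picked from.
#'
#' @param n Number of peptides.
#' @param length Total peptide length including linker (default 20).
#' @param linker Fixed C-terminal residues (default "GSC").
#' @param seed Integer seed.
#' @return Tibble with columns `name`, `sequence`.
#' @export
simulate_random_library <- function(n, length = 20, linker = "GSC", seed = 1L) {
  if (n < 1L) abort("`n` must be >= 1.")
  n_rand <- length - nchar(linker)
  if (n_rand < 1L) abort("`length` must exceed the linker length.")
  withr::with_seed(derive_seed(seed, 5L), {
    seqs <- vapply(seq_len(n), function(i) {
      paste0(paste(sample(amino_acids(), n_rand, replace = TRUE), collapse = ""),
             linker)
    }, character(1))
  })
  tibble::tibble(name = sprintf("rand%04d", seq_len(n)), sequence = seqs)
}
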