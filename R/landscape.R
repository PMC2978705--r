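# Ground-truth energy landscapes for the simulator: an additive
# per-(position, residue) contribution table plus optional adjacent-pair
# coupling. Positive coupling weakens binding relative to the additive sum
# (sub-additivity from nearest-neighbour interference); negative coupling
# (cooperativity) is allowed but off by default since it is not what short
# unstructured peptides show.

#' Construct a ground-truth energy landscape
#'
#' @param lead A [peptide()].
#' @param lead_dg Lead standard binding free energy, kcal/mol.
#' @param contributions Tibble with columns `position`, `residue`, `ddg`
#'   (kcal/mol). Entries for the lead's own residue must be zero (they are
#'   checked, and missing identity entries are implied zero).
#' @param coupling Optional tibble with columns `pos_i`, `pos_j`, `epsilon`
#'   (kcal/mol); pairs must be adjacent (`pos_j == pos_i + 1`). Epsilon is
#'   added when both positions carry non-wild substitutions.
#' @param temperature Kelvin.
#' @return An `energy_landscape`.
#' @export
energy_landscape <- function(lead, lead_dg, contributions,
                             coupling = NULL, temperature = 298.15) {
  lead <- as_peptide(lead)
  stopifnot_scalar_number(lead_dg, "lead_dg")
  contributions <- tibble::as_tibble(contributions)
  if (!all(c("position", "residue", "ddg") %in% names(contributions))) {
    abort("`contributions` needs columns `position`, `residue`, `ddg`.")
  }
  if (any(contributions$position < 1L | contributions$position > randomized_length(lead))) {
    abort("Contribution positions must lie in the randomized region.")
  }
  wild_at <- substring(lead$residues, contributions$position, contributions$position)
  identity_rows <- contributions$residue == wild_at
  if (any(identity_rows & contributions$ddg != 0)) {
    abort("Identity (wild-residue) contributions must be zero.")
  }
  if (!is.null(coupling)) {
    coupling <- tibble::as_tibble(coupling)
    if (!all(c("pos_i", "pos_j", "epsilon") %in% names(coupling))) {
      abort("`coupling` needs columns `pos_i`, `pos_j`, `epsilon`.")
    }
    if (any(coupling$pos_j != coupling$pos_i + 1L)) {
      abort("Coupling is nearest-neighbour only: pos_j must equal pos_i + 1.")
    }
  }
  structure(
    list(
      lead = lead,
      lead_dg = lead_dg,
      contributions = contributions,
      coupling = coupling %||% tibble::tibble(pos_i = integer(0), pos_j = integer(0), epsilon = numeric(0)),
      temperature = temperature
    ),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  n_enh <- sum(x$contributions$ddg < 0)
  cat(sprintf(
    "Energy landscape on %s: lead dG = %.2f kcal/mol (Kd %s), %d table entries (%d enhancing), %d coupled pairs\n",
    x$lead$name, x$lead_dg, format_kd(exp(x$lead_dg / rt_kcal(x$temperature))),
    nrow(x$contributions), n_enh, nrow(x$coupling)
  ))
  invisible(x)
}

#' Draw a random ground-truth landscape
#'
#' A reproducible statistical stand-in for a real target: exactly
#' `n_enhancing` (position, residue) entries get a negative contribution
#' drawn uniformly from `ddg_range`; the remaining non-identity entries get
#' a mildly detrimental contribution from `detrimental_range`; identity
#' entries are zero. Each adjacent position pair independently receives a
#' coupling term with probability `coupling_prob`, with magnitude drawn from
#' `coupling_strength` (positive = sub-additive).
#'
#' @param lead A [peptide()].
#' @param n_enhancing Number of enhancing entries (default 5, the scale of
#'   a productive point-variant scan).
#' @param ddg_range Range the enhancing contributions are drawn from,
#'   kcal/mol (default c(-0.9, -0.5), matching observed single-substitution
#'   gains).
#' @param alphabet Substitution letters the table covers.
#' @param positions Positions the table covers (default all randomized).
#' @param lead_dg Lead free energy (default -5.21 kcal/mol, a
#'   high-micromolar lead).
#' @param detrimental_range Range for non-enhancing entries (default
#'   c(0, 0.5)).
#' @param coupling_prob Per-adjacent-pair probability of a coupling term.
#' @param coupling_strength Magnitude range for epsilon, kcal/mol.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param temperature Kelvin.
#' @return An [energy_landscape()].
#' @export
random_landscape <- function(lead,
                             n_enhancing = 5,
                             ddg_range = c(-0.9, -0.5),
                             alphabet = c("Y", "A", "D", "S", "K", "N", "V", "W"),
                             positions = NULL,
                             lead_dg = -5.21,
                             detrimental_range = c(0, 0.5),
                             coupling_prob = 0,
                             coupling_strength = c(0.3, 0.7),
                             seed = 1L,
                             temperature = 298.15) {
  lead <- as_peptide(lead)
  if (is.null(positions)) positions <- seq_len(randomized_length(lead))
  cells <- enumerate_variants(lead, alphabet = alphabet, positions = positions,
                              mode = "exclude_identity")
  if (n_enhancing > nrow(cells)) {
    abort(sprintf("`n_enhancing` (%d) exceeds the %d available non-identity cells.",
                  n_enhancing, nrow(cells)))
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(cells), n_enhancing)
    ddg <- runif(nrow(cells), detrimental_range[1], detrimental_range[2])
    ddg[idx] <- runif(n_enhancing, ddg_range[1], ddg_range[2])
    coupling <- NULL
    if (coupling_prob > 0) {
      pairs <- tibble::tibble(pos_i = head(positions, -1), pos_j = head(positions, -1) + 1L)
      pairs <- dplyr::filter(pairs, .data$pos_j %in% positions)
      keep <- runif(nrow(pairs)) < coupling_prob
      if (any(keep)) {
        coupling <- pairs[keep, ]
        coupling$epsilon <- runif(sum(keep), coupling_strength[1], coupling_strength[2])
      }
    }
    energy_landscape(
      lead, lead_dg,
      contributions = tibble::tibble(
        position = cells$position, residue = cells$sub, ddg = ddg
      ),
      coupling = coupling,
      temperature = temperature
    )
  })
}

#' True standard binding free energy of a variant set under a landscape
#'
#' The additive part is the lead free energy plus the tabulated
#' contributions of each substitution; every adjacent pair of substituted
#' positions that carries a coupling term adds its epsilon on top.
#'
#' @param landscape An [energy_landscape()].
#' @param codes Character vector of variant codes (empty = the lead).
#' @return Free energy in kcal/mol.
#' @export
true_dg <- function(landscape, codes) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(codes) == 0L) return(landscape$lead_dg)
  vs <- parse_variants(codes, landscape$lead)
  if (anyDuplicated(vs$position)) abort("Duplicate positions in variant set.")
  tab <- landscape$contributions
  ddg <- purrr::map2_dbl(vs$position, vs$sub, function(p, s) {
    if (s == substr(landscape$lead$residues, p, p)) return(0)
    hit <- tab$ddg[tab$position == p & tab$residue == s]
    if (length(hit) == 0L) {
      abort(sprintf("No landscape entry for position %d residue %s.", p, s))
    }
    hit[[1]]
  })
  subbed <- sort(vs$position[vs$sub != vs$wild])
  eps <- 0
  if (nrow(landscape$coupling) > 0 && length(subbed) > 1) {
    cp <- landscape$coupling
    hit <- cp$pos_i %in% subbed & cp$pos_j %in% subbed
    eps <- sum(cp$epsilon[hit])
  }
  landscape$lead_dg + sum(ddg) + eps
}

#' True dissociation constant of a variant set under a landscape
#' @inheritParams true_dg
#' @return Kd in molar.
#' @export
true_kd <- function(landscape, codes) {
  exp(true_dg(landscape, codes) / rt_kcal(landscape$temperature))
}
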