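#' Construct a peptide sequence
#'
#' A peptide is a named string of one-letter amino-acid codes with a fixed
#' C-terminal linker region (by convention the "GSC" tail shared by all
#' library members, used for surface attachment and labeling). Only the
#' N-terminal "randomized" region, positions `1..(length - linker_length)`,
#' is eligible for point variation.
#'
#' @param residues Character scalar of one-letter codes (canonical 20).
#' @param name Identifier for the peptide.
#' @param linker_length Number of fixed C-terminal residues (default 3).
#' @return An object of class `peptide`.
#' @examples
#' peptide("FERDPLMMPWSFLQSRQGSC", name = "TNF1")
#' @export
peptide <- function(residues, name = "peptide", linker_length = 3L) {
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) == 0L) {
    abort("`residues` must be a non-empty character scalar.")
  }
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(chars, amino_acids())
  if (length(bad) > 0L) {
    abort(sprintf("Non-canonical residue code(s): %s", paste(unique(bad), collapse = ", ")))
  }
  linker_length <- as.integer(linker_length)
  if (linker_length < 0L || linker_length >= nchar(residues)) {
    abort("`linker_length` must be non-negative and smaller than the peptide length.")
  }
  structure(
    list(name = name, residues = residues, linker_length = linker_length),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf(
    ">%s  (%d aa, %d randomized + %d linker)\n%s\n",
    x$name, nchar(x$residues), randomized_length(x), x$linker_length, x$residues
  ))
  invisible(x)
}

#' @export
as.character.peptide <- function(x, ...) x$residues

is_peptide <- function(x) inherits(x, "peptide")

as_peptide <- function(x, name = "peptide") {
  if (is_peptide(x)) x else peptide(x, name = name)
}

#' Length of the variable (non-linker) region of a peptide
#' @param x A [peptide()].
#' @return Integer count of randomized positions.
#' @export
randomized_length <- function(x) {
  x <- as_peptide(x)
  nchar(x$residues) - x$linker_length
}

#' Lead peptides of the TNF-alpha / transferrin optimization study
#'
#' The three low-affinity 20-mer leads used throughout the package examples:
#' TNF1 and TNF4 bind tumor-necrosis factor alpha, TRF26 binds transferrin.
#' All carry the common C-terminal GSC linker.
#'
#' @param which One of "TNF1", "TNF4", "TRF26".
#' @return A [peptide()].
#' @examples
#' lead_peptide("TNF1")
#' @export
lead_peptide <- function(which = c("TNF1", "TNF4", "TRF26")) {
  which <- match.arg(which)
  seqs <- c(
    TNF1  = "FERDPLMMPWSFLQSRQGSC",
    TNF4  = "YGPSDAFKITRFHQQSSGSC",
    TRF26 = "AHKVVPQRQIRHAYNRYGSC"
  )
  peptide(seqs[[which]], name = which, linker_length = 3L)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues (linker included), the
#' standard solubility proxy used to triage lead candidates. The scale is
#' carried in exact tenths internally so that `digits`-place rounding of the
#' mean follows decimal (half-away-from-zero) arithmetic rather than binary
#' floating point.
#'
#' @param x A [peptide()] or character vector of sequences.
#' @param digits Optional number of decimals to round to (I/O convention is
#'   2); `NULL` returns the full-precision mean.
#' @return Numeric vector of GRAVY scores.
#' @examples
#' gravy(lead_peptide("TNF1"), digits = 2) # -0.52
#' @export
gravy <- function(x, digits = NULL) {
  seqs <- if (is_peptide(x)) x$residues else as.character(x)
  vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    if (!all(chars %in% amino_acids())) abort("Non-canonical residue in sequence.")
    tenths <- sum(.kd_hydropathy_tenths[chars])
    n <- length(chars)
    if (is.null(digits)) {
      tenths / (10 * n)
    } else {
      # mean in units of 10^-digits, computed before any binary rounding loss
      round_half_up(tenths * 10^(digits - 1) / n) / 10^digits
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water. Average (not monoisotopic)
#' masses are used because SPR response units scale with the average mass of
#' bound material, which is what molecular-weight-adjusted screen responses
#' require.
#'
#' @param x A [peptide()] or character vector of sequences.
#' @return Numeric vector of masses in Da.
#' @examples
#' molecular_weight("G") # 75.07
#' @export
molecular_weight <- function(x) {
  seqs <- if (is_peptide(x)) x$residues else as.character(x)
  vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    if (!all(chars %in% amino_acids())) abort("Non-canonical residue in sequence.")
    sum(.aa_avg_mass[chars]) + .water_avg_mass
  }, numeric(1), USE.NAMES = FALSE)
}
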