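# Amino-acid reference tables. Hydropathy is stored in tenths (integers) so
# that GRAVY means can be rounded in exact decimal arithmetic.

#' The canonical 20 one-letter amino-acid codes
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Kyte-Doolittle hydropathy, in tenths of a unit
.kd_hydropathy_tenths <- c(
  A =  18, R = -45, N = -35, D = -35, C =  25,
  Q = -35, E = -35, G =  -4, H = -32, I =  45,
  L =  38, K = -39, M =  19, F =  28, P = -16,
  S =  -8, T =  -7, W =  -9, Y = -13, V =  42
)

#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kyte_doolittle <- function() .kd_hydropathy_tenths / 10

# Average (not monoisotopic) residue masses, Da. SPR response units scale
# with the average mass of bound material, so average masses are the right
# choice for molecular-weight-adjusted responses.
.aa_avg_mass <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

.water_avg_mass <- 18.01528
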