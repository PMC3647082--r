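# Frozen physical constants used throughout the package. All masses are
# monoisotopic, in Da. These are the only copies: every mass computation in
# the package goes through this file.

# Monoisotopic residue (not free amino acid) masses for the 20 standard
# residues, Da.
AA_MONO <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

WATER_MONO  <- 18.010565  # H2O, added once per peptide
PROTON_MONO <- 1.007276   # charge carrier for m/z
CARBAMIDOMETHYL_MONO <- 57.021464  # fixed Cys alkylation (+C2H3NO)

# Kyte-Doolittle hydropathy index per residue (dimensionless, -4.5..4.5).
KYTE_DOOLITTLE <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Same index rescaled to [0, 1]; used as the detectability attenuation scale
# in the synthetic-data model.
KYTE_DOOLITTLE_01 <- (KYTE_DOOLITTLE + 4.5) / 9

STANDARD_AA <- names(AA_MONO)

# Nonstandard letters tolerated in FASTA input; peptides containing them have
# undefined mass and are excluded from observable-peptide counting.
NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

LOCALIZATION_LEVELS <- c("thylakoid", "envelope", "stroma", "other", "unknown")

#' Mean Kyte-Doolittle hydropathy of a peptide, rescaled to [0, 1]
#'
#' Computes the per-residue mean of the Kyte-Doolittle hydropathy index,
#' linearly rescaled so that 0 is the most hydrophilic residue (Arg, -4.5)
#' and 1 the most hydrophobic (Ile, +4.5). Used by the synthetic-data model
#' to attenuate peptide detection probability, emulating the depressed
#' recovery of very hydrophobic membrane subunits in LC-MS/MS.
#'
#' @param sequence Character vector of peptide sequences (standard residues).
#' @return Numeric vector in \[0, 1\], one value per input sequence.
#' @examples
#' peptide_hydropathy(c("IIII", "RRRR", "GASP"))
#' @export
peptide_hydropathy <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- setdiff(res, STANDARD_AA)
    if (length(bad) > 0L) {
      stop("hydropathy undefined for nonstandard residue(s): ",
           paste(unique(bad), collapse = ", "))
    }
    mean(KYTE_DOOLITTLE_01[res])
  }, numeric(1L), USE.NAMES = FALSE)
}
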