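# Residue groups, per-residue scales and the pKa table used by the default
# feature registry. All tables are plain named vectors so users can inspect
# or override them through the config (see default_config()).

#' Default physicochemical residue groups
#'
#' Sixteen named residue groups used for group-composition and
#' maximum-consecutive-run features. The first seven are taken from the
#' field's conventional definitions (basic and positively charged residues
#' H/K/R; sulfur-containing C/M; aliphatic I/L/V/A/G; non-polar and
#' hydrophilic I/L/V/A/G/P; acidic and negatively charged D/E); the rest are
#' standard auxiliary classes (aromatic, polar, tiny, ...).
#'
#' @return Named list of character vectors of residue letters.
#' @export
residue_groups <- function() {
  list(
    bpc         = c("H", "K", "R"),
    anc         = c("D", "E"),
    charged     = c("D", "E", "H", "K", "R"),
    sulfur      = c("C", "M"),
    aromatic    = c("F", "H", "W", "Y"),
    aliphatic   = c("I", "L", "V", "A", "G"),
    nph         = c("I", "L", "V", "A", "G", "P"),
    polar       = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"),
    nonpolar    = c("A", "F", "G", "I", "L", "M", "P", "V"),
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V"),
    hydrophilic = c("D", "E", "H", "K", "N", "Q", "R"),
    tiny        = c("A", "C", "G", "S", "T"),
    small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    large       = c("F", "I", "K", "L", "M", "R", "W", "Y"),
    hydroxyl    = c("S", "T", "Y"),
    amide       = c("N", "Q")
  )
}

# Kyte-Doolittle hydropathy (J Mol Biol 1982).
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# Chou-Fasman secondary-structure propensities (helix Pa, sheet Pb, turn Pt).
CF_HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)
CF_SHEET <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
  G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
  M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
  S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)
CF_TURN <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60,
  G = 1.56, H = 0.95, I = 0.47, K = 1.01, L = 0.59,
  M = 0.60, N = 1.56, P = 1.52, Q = 0.98, R = 0.95,
  S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)

# TOP-IDP intrinsic-disorder propensity (Campen et al. 2008); higher means
# more disorder-promoting.
TOP_IDP <- c(
  A =  0.060, C =  0.020, D =  0.192, E =  0.736, F = -0.697,
  G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
  M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
  S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510)

# Classic disorder-promoting residue set (used for the disordered-residue
# count stand-in).
DISORDER_PRONE <- c("A", "E", "G", "K", "P", "Q", "R", "S")

# Side-chain and terminal pKa values (EMBOSS convention).
PKA_TABLE <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(H = 6.5, K = 10.8, R = 12.5),
  negative = c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1)
)
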