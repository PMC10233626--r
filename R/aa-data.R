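# Residue-level lookup tables used across the package.

# 3-letter -> 1-letter, including common modified residues mapped to their
# parent amino acid (MSE -> M etc.); anything else becomes 'X'.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", CSO = "C", PTR = "Y",
  SEP = "S", TPO = "T", HYP = "P", MLY = "K"
)

#' Convert three-letter residue names to one-letter codes
#'
#' Standard amino acids and a small set of common modified residues (e.g.
#' `MSE`) are mapped; unknown names become `"X"`.
#'
#' @param resname Character vector of three-letter residue names.
#' @return Character vector of one-letter codes.
#' @examples
#' aa321(c("ALA", "MSE", "UNK"))
#' @export
aa321 <- function(resname) {
  out <- unname(AA_321[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

# Kyte-Doolittle hydropathy scale (J Mol Biol 157, 105-132).
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

HYDROPHOBICITY_SCALES <- list(kyte_doolittle = KYTE_DOOLITTLE)

# Per-residue contribution to net charge at pH 7: R/K +1, H +0.5 (pKa ~6.5),
# D/E -1; everything else 0.
CHARGE_AT_PH7 <- c(R = 1, K = 1, H = 0.5, D = -1, E = -1)
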