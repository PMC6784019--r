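# Physical constants and residue tables used across the package.
# Monoisotopic values are stated to >= 5 decimals and fixed here, in one
# place, so the mass calculator, the MALDI simulator and the matchers can
# never drift apart.

#' Mass and modification constants
#'
#' Named numeric vector of the constants used by the mass module
#' (monoisotopic, Da): water, proton, hydrogen, the carbamidomethyl and
#' methionine-oxidation deltas, the C-terminal amidation delta and the
#' per-disulfide delta (loss of two hydrogens).
#'
#' @return Named numeric vector of constants in Da.
#' @examples
#' massConstants()[["water"]]
#' @export
massConstants <- function() {
  c(
    water           = 18.010565,
    water_avg       = 18.01528,
    proton          = 1.007276,
    hydrogen        = 1.0078250319,
    carbamidomethyl = 57.02146,
    met_oxidation   = 15.99491,
    c_term_amide    = -0.98402,
    disulfide       = -2 * 1.0078250319
  )
}

# Monoisotopic residue masses (Da), standard 20 amino acids.
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da).
.AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# Kyte-Doolittle hydropathy scale.
.KD_SCALE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Residues counted as "small" for the (-3,-1) signal-cleavage rule.
.SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

# Standard codon table, amino acid -> synonymous codons (DNA alphabet).
.CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"), `*` = c("TAA", "TAG", "TGA")
)

.AA20 <- names(.MONO_RESIDUE)

.checkAaString <- function(seq, what = "sequence", allow_x = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string")
  allowed <- .AA20
  if (allow_x) allowed <- c(allowed, "X")
  bad <- setdiff(strsplit(seq, "")[[1]], allowed)
  if (length(bad))
    stop(what, " contains illegal residue(s): ", paste(unique(bad), collapse = ", "))
  invisible(seq)
}
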