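# Independent oracles used to cross-check the implementation.
# Each is computed by a different route than the package code:
#  - peptide masses from elemental composition x atomic masses;
#  - local alignment by a plain Gotoh dynamic program written here;
#  - signature matching by recursive backtracking over parsed tokens.

# residue elemental composition (C, H, N, O, S)
.ORACLE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

.ORACLE_ATOM <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

oracleMass <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  comp <- Reduce(`+`, .ORACLE_FORMULA[aa])
  comp[2] <- comp[2] + 2  # + H2O
  comp[4] <- comp[4] + 1
  sum(comp * .ORACLE_ATOM)
}

# Gotoh local alignment; a gap of length g costs open + g * ext
# (open, ext given as positive costs here).
oracleLocalScore <- function(q, t, mat, open = 10, ext = 1) {
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  n <- length(qa); m <- length(ta)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    d <- max(M[i, j], Ix[i, j], Iy[i, j]) + mat[qa[i], ta[j]]
    M[i + 1, j + 1] <- max(0, d)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# recursive backtracking matcher over parsed signature tokens
oracleSignatureMatch <- function(seq, toks) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  rec <- function(ti, pos) {
    if (ti > length(toks)) return(TRUE)
    t <- toks[[ti]]
    if (t$type == "lit") {
      pos <= n && aa[pos] == t$residue && rec(ti + 1, pos + 1)
    } else if (t$type == "class") {
      pos <= n && aa[pos] %in% t$residues && rec(ti + 1, pos + 1)
    } else if (t$type == "spacer") {
      any(vapply(t$lengths, function(k)
        pos + k - 1 <= n && rec(ti + 1, pos + k), logical(1)))
    } else {  # any
      any(vapply(0:(n - pos + 1), function(k)
        pos + k - 1 <= n && rec(ti + 1, pos + k), logical(1)))
    }
  }
  any(vapply(seq_len(n + 1), function(p) rec(1, p), logical(1)))
}

AA20 <- names(.ORACLE_FORMULA)

randomPeptide <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
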