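# Cysteine frameworks and superfamily classification.
#
# The framework of a disulfide-rich peptide records the order and
# adjacency of its cysteines only: consecutive cysteines collapse to a
# doublet token ("CC", or "CCC" for triplets), any non-zero spacer becomes
# "-". Exact spacer lengths are deliberately NOT part of the canonical
# pattern -- superfamilies with the same cysteine count are distinguished
# purely by where the doublet sits.

#' CysteineFramework class
#'
#' Ordered cysteine positions of a peptide plus the canonical
#' order/adjacency pattern derived from them.
#'
#' @slot peptideRef Identifier of the source peptide.
#' @slot positions Integer vector of 0-based cysteine indices, ascending.
#' @slot canonical Canonical pattern string, e.g. \code{"C-C-CC-C"}.
#' @slot spacings Integer vector of inter-cysteine gap lengths (residues
#'   strictly between consecutive cysteines).
#' @exportClass CysteineFramework
setClass("CysteineFramework",
  representation(peptideRef = "character", positions = "integer",
                 canonical = "character", spacings = "integer"),
  prototype(peptideRef = NA_character_, positions = integer(0),
            canonical = "", spacings = integer(0)))

setValidity("CysteineFramework", function(object) {
  p <- object@positions
  msg <- character(0)
  if (is.unsorted(p, strictly = TRUE) && length(p) > 1L)
    msg <- c(msg, "positions must be strictly increasing")
  if (any(p < 0L)) msg <- c(msg, "positions must be >= 0")
  n_tok <- nchar(gsub("-", "", object@canonical, fixed = TRUE))
  if (n_tok != length(p))
    msg <- c(msg, "canonical pattern cysteine count disagrees with positions")
  if (length(p) > 1L && !identical(object@spacings, diff(p) - 1L))
    msg <- c(msg, "spacings disagree with positions")
  if (length(msg)) msg else TRUE
})

#' @describeIn extractFramework Number of cysteines in a framework.
#' @export
setGeneric("nCysteines", function(x) standardGeneric("nCysteines"))
setMethod("nCysteines", "CysteineFramework", function(x) length(x@positions))

#' @describeIn extractFramework Canonical pattern string accessor.
#' @export
setGeneric("canonicalPattern", function(x) standardGeneric("canonicalPattern"))
setMethod("canonicalPattern", "CysteineFramework", function(x) x@canonical)

#' @describeIn extractFramework 0-based cysteine position accessor.
#' @export
setGeneric("cysteinePositions", function(x) standardGeneric("cysteinePositions"))
setMethod("cysteinePositions", "CysteineFramework", function(x) x@positions)

setMethod("show", "CysteineFramework", function(object) {
  cat("CysteineFramework for", object@peptideRef, "\n",
      " cysteines:", length(object@positions),
      " pattern:", if (nchar(object@canonical)) object@canonical else "(none)",
      "\n")
})

# order/adjacency pattern from 0-based positions
.canonicalFromPositions <- function(pos) {
  if (!length(pos)) return("")
  if (length(pos) == 1L) return("C")
  gaps <- diff(pos)
  paste0("C", paste(vapply(gaps, function(g) if (g == 1L) "C" else "-C",
                           character(1)), collapse = ""))
}

#' Extract the cysteine framework of a mature peptide
#'
#' @param mature Amino-acid string (may contain \code{X}).
#' @param peptide_ref Identifier stored in the result.
#' @return A \linkS4class{CysteineFramework}. A cysteine-free sequence
#'   yields an empty framework.
#' @examples
#' canonicalPattern(extractFramework("ACDDCEECCFFC"))  # "C-C-CC-C"
#' @export
extractFramework <- function(mature, peptide_ref = NA_character_) {
  if (nchar(mature)) .checkAaString(mature, "mature", allow_x = TRUE)
  aa <- strsplit(mature, "")[[1]]
  pos <- as.integer(which(aa == "C") - 1L)
  new("CysteineFramework", peptideRef = peptide_ref, positions = pos,
      canonical = .canonicalFromPositions(pos),
      spacings = if (length(pos) > 1L) diff(pos) - 1L else integer(0))
}

#' Superfamily definitions (classification scheme)
#'
#' Loads a superfamily scheme: one row per superfamily with its canonical
#' cysteine pattern, cysteine count, mature-length range and (annotation
#' only) validated disulfide connectivity and free cysteines. The shipped
#' default is the eight-superfamily scheme observed in the
#' \emph{Pamphobeteus verdolaga} venom gland.
#'
#' @param path Optional path to a user TSV overriding the shipped scheme
#'   (same columns).
#' @return data.frame with columns \code{superfamily}, \code{canonical},
#'   \code{n_cys}, \code{len_min}, \code{len_max}, \code{connectivity},
#'   \code{free_cys}, \code{notes}.
#' @examples
#' superfamilyDefinitions()$canonical
#' @export
superfamilyDefinitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "superfamilies.tsv", package = "knotminer")
  defs <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  defs$n_cys <- as.integer(defs$n_cys)
  defs$len_min <- as.integer(defs$len_min)
  defs$len_max <- as.integer(defs$len_max)
  counted <- vapply(defs$canonical, function(p)
    nchar(gsub("-", "", p, fixed = TRUE)), integer(1))
  if (any(counted != defs$n_cys))
    stop("definition n_cys disagrees with canonical pattern for: ",
         paste(defs$superfamily[counted != defs$n_cys], collapse = ", "))
  if (anyDuplicated(defs$canonical))
    stop("duplicate canonical patterns in superfamily definitions")
  defs
}

#' Classify a framework against a superfamily scheme
#'
#' Exact match on the canonical cysteine pattern. A mature length outside
#' the superfamily's observed range produces a warning flag in the result,
#' never a rejection; a pattern absent from the scheme is \code{"novel"}.
#'
#' @param fw A \linkS4class{CysteineFramework} (or canonical pattern
#'   string).
#' @param defs Superfamily definitions
#'   (\code{\link{superfamilyDefinitions}()}).
#' @param mature_len Optional mature length for the length-range check.
#' @return List with \code{superfamily} (\code{"SF1"}..., or
#'   \code{"novel"}) and \code{length_warning} (logical).
#' @examples
#' classifySuperfamily(extractFramework("ACDDCEECCFFC"))$superfamily
#' @export
classifySuperfamily <- function(fw, defs = superfamilyDefinitions(),
                                mature_len = NA_integer_) {
  if (anyDuplicated(defs$canonical))
    stop("duplicate canonical patterns in superfamily definitions")
  pat <- if (is(fw, "CysteineFramework")) canonicalPattern(fw) else fw
  hit <- match(pat, defs$canonical)
  if (is.na(hit))
    return(list(superfamily = "novel", length_warning = FALSE))
  lw <- !is.na(mature_len) &&
    (mature_len < defs$len_min[hit] || mature_len > defs$len_max[hit])
  list(superfamily = defs$superfamily[hit], length_warning = lw)
}

#' Partition frameworks by canonical pattern
#'
#' Groups a list of frameworks (or canonical strings) by their canonical
#' pattern. Group naming is deterministic by first occurrence and the
#' partition is invariant under permutation of the input.
#'
#' @param fws List of \linkS4class{CysteineFramework} objects or character
#'   vector of canonical patterns.
#' @return Named list mapping canonical pattern to the integer indices of
#'   its members, in first-occurrence order of patterns.
#' @examples
#' length(clusterFrameworks(c("C-C", "C-C", "CC")))  # 2
#' @export
clusterFrameworks <- function(fws) {
  if (!length(fws)) return(structure(list(), names = character(0)))
  pats <- if (is.character(fws)) fws
          else vapply(fws, canonicalPattern, character(1))
  split(seq_along(pats), factor(pats, levels = unique(pats)))
}

#' Validate a disulfide-connectivity assignment
#'
#' Checks that a set of cysteine pairings over a framework is physically
#' admissible: 1-based indices in range, no self-pairing, no cysteine used
#' twice. Unpaired cysteines are returned as the free list. This validates
#' connectivity given as data; the package never predicts connectivity.
#'
#' @param fw \linkS4class{CysteineFramework} or an integer cysteine count.
#' @param bonds List of length-2 integer vectors (1-based cysteine
#'   indices).
#' @return List with \code{valid} (logical), \code{reason} (\code{NA} when
#'   valid) and \code{free} (integer vector of unpaired cysteine indices).
#' @examples
#' validateConnectivity(6, list(c(1, 4), c(2, 5), c(3, 6)))$valid
#' @export
validateConnectivity <- function(fw, bonds) {
  n <- if (is(fw, "CysteineFramework")) nCysteines(fw) else as.integer(fw)
  used <- integer(0)
  for (b in bonds) {
    b <- as.integer(b)
    if (length(b) != 2L)
      return(list(valid = FALSE, reason = "bond is not a pair", free = integer(0)))
    if (b[1] == b[2])
      return(list(valid = FALSE, reason = "self-paired cysteine", free = integer(0)))
    if (any(b < 1L) || any(b > n))
      return(list(valid = FALSE, reason = "cysteine index out of range",
                  free = integer(0)))
    if (any(b %in% used))
      return(list(valid = FALSE, reason = "cysteine reused", free = integer(0)))
    used <- c(used, b)
  }
  list(valid = TRUE, reason = NA_character_, free = setdiff(seq_len(n), used))
}

#' Position frequency / information matrix for a sequence logo
#'
#' Column-wise residue frequencies and Shannon information content (bits,
#' uniform background over the 20 standard residues) for a gapped
#' alignment. Gap characters \code{-} are excluded from the frequencies.
#'
#' @param aligned Character vector of equal-length aligned sequences.
#' @return List with \code{frequencies} (20 x L matrix, columns sum to 1
#'   where any residue is present) and \code{information} (numeric, bits
#'   per column, in \code{[0, log2(20)]}).
#' @examples
#' consensusLogoMatrix(c("CAT", "CAT"))$information[1]  # log2(20)
#' @export
consensusLogoMatrix <- function(aligned) {
  if (!length(aligned)) stop("empty alignment")
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("ragged alignment: sequences differ in length")
  mat <- do.call(rbind, strsplit(aligned, ""))
  bad <- setdiff(unique(as.vector(mat)), c(.AA20, "X", "-"))
  if (length(bad)) stop("illegal characters in alignment: ",
                        paste(bad, collapse = ", "))
  freq <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col %in% .AA20]
    if (!length(col)) { info[j] <- 0; next }
    tab <- table(factor(col, levels = .AA20))
    f <- as.numeric(tab) / length(col)
    freq[, j] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    info[j] <- log2(20) - h
  }
  list(frequencies = freq, information = info)
}
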