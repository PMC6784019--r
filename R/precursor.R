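# Precursor architecture: signal peptide + propeptide + mature peptide.
#
# Spider toxin precursors are secreted: an N-terminal signal peptide is
# removed by signal peptidase and, in most families, a short acidic
# propeptide is then cleaved after an arginine preceded by a glutamate
# within three residues (the processing quadruplet motif, PQM). Both
# cleavages are predicted here with explicit, dependency-free rules.

#' Predict the signal-peptide cleavage site
#'
#' Heuristic stand-in for a learned signal-peptide model. A candidate
#' protein must carry a hydrophobic core: some 7-residue window starting
#' within residues 2-20 whose mean Kyte-Doolittle hydropathy reaches
#' \code{core_threshold}. Cleavage sites are positions 10-35 (cleave after
#' that residue) satisfying the small-residue rule at -3 and -1
#' (A, G, S, C or T) where any such site exists. Each admissible site is
#' scored as the mean hydropathy of the 7 residues ending at its -2
#' position minus the mean hydropathy of the 3 residues following the cut:
#' a true site sits just past the hydrophobic h-region, at the start of the
#' polar/charged c-region, so the drop is maximal there. Ties go to the
#' earliest site.
#'
#' @param protein Amino-acid string starting with \code{M}, length >= 25.
#' @param core_threshold Mean Kyte-Doolittle hydropathy a 7-mer window must
#'   reach for the protein to count as having a signal (default 1.6).
#' @param site_range Admissible cleavage positions, cleave-after residue
#'   index, 1-based (default \code{c(10, 35)}).
#' @return List with \code{position} (cleave after this many residues;
#'   \code{NA} for "no signal"), \code{score} (hydrophobic-core strength,
#'   mean KD of the best 7-mer), and \code{has_signal}.
#' @examples
#' predictSignalCleavage("MKTLVLVAVLGLALAEDAESEEARIFECVFSC")
#' @export
predictSignalCleavage <- function(protein, core_threshold = 1.6,
                                  site_range = c(10L, 35L)) {
  .checkAaString(protein, "protein", allow_x = TRUE)
  if (substr(protein, 1, 1) != "M") stop("protein must start with M")
  n <- nchar(protein)
  if (n < 25L) stop("protein shorter than 25 residues")
  aa <- strsplit(protein, "")[[1]]
  kd <- unname(.KD_SCALE[aa])
  kd[is.na(kd)] <- 0  # X residues are neutral
  win_mean <- function(i, j) mean(kd[i:j])
  # hydrophobic core: best 7-mer starting in residues 2..20
  starts <- 2:min(20L, n - 6L)
  core <- max(vapply(starts, function(s) win_mean(s, s + 6L), numeric(1)))
  if (core < core_threshold)
    return(list(position = NA_integer_, score = core, has_signal = FALSE))
  lo <- max(site_range[1], 10L)
  hi <- min(site_range[2], n - 10L)  # keep a non-trivial mature part
  if (lo > hi)
    return(list(position = NA_integer_, score = core, has_signal = FALSE))
  cand <- lo:hi
  ok <- aa[cand] %in% .SMALL_RESIDUES & aa[cand - 2L] %in% .SMALL_RESIDUES
  if (any(ok)) cand <- cand[ok]
  site_score <- vapply(cand, function(p) {
    up <- win_mean(max(1L, p - 8L), p - 2L)
    down <- win_mean(p + 1L, min(n, p + 3L))
    up - down
  }, numeric(1))
  best <- cand[which.max(site_score)]  # which.max: earliest on ties
  list(position = as.integer(best), score = core, has_signal = TRUE)
}

#' Predict the propeptide cleavage site (processing quadruplet rule)
#'
#' The propeptide of a spider-toxin precursor typically ends in a
#' processing quadruplet: arginine at -1 with at least one glutamate among
#' positions -2..-4. Cleavage is placed after such an R; among candidates,
#' the last one occurring before the first cysteine is chosen (the mature
#' domain of a disulfide-rich peptide begins at or just before its first
#' cysteine). With no admissible site the mature peptide starts at offset 0
#' (no propeptide).
#'
#' @param post_signal Amino-acid string following the signal peptide.
#' @return List with \code{offset} (0-based mature start within
#'   \code{post_signal}) and \code{rule} (\code{"PQM"} or
#'   \code{"fallback"}).
#' @examples
#' predictPropeptideCleavage("SEEERIFECVFSCDIEK")$offset  # 5
#' @export
predictPropeptideCleavage <- function(post_signal) {
  .checkAaString(post_signal, "post_signal", allow_x = TRUE)
  aa <- strsplit(post_signal, "")[[1]]
  first_c <- match("C", aa)
  limit <- if (is.na(first_c)) length(aa) else first_c - 1L
  cand <- which(aa == "R")
  cand <- cand[cand <= limit & cand >= 2L]
  cand <- cand[vapply(cand, function(p) {
    any(aa[max(1L, p - 3L):(p - 1L)] == "E")
  }, logical(1))]
  if (!length(cand)) return(list(offset = 0L, rule = "fallback"))
  list(offset = max(cand), rule = "PQM")
}

#' Segment an ORF protein into signal, propeptide and mature peptide
#'
#' Applies \code{\link{predictSignalCleavage}} then
#' \code{\link{predictPropeptideCleavage}} and returns the three segments,
#' whose concatenation always equals the input exactly. Proteins with no
#' detectable signal are returned whole as the mature peptide and flagged;
#' mature peptides shorter than 10 residues are flagged, never dropped.
#'
#' @param protein ORF protein string (starts with \code{M}).
#' @param orf_id Identifier carried into the result.
#' @param core_threshold Passed to \code{\link{predictSignalCleavage}}.
#' @return List with \code{orf_id}, \code{signal}, \code{propeptide},
#'   \code{mature}, \code{signal_score}, \code{cleavage_rule}
#'   (\code{"PQM"}, \code{"fallback"} or \code{"no_signal"}) and
#'   \code{flags} (character vector; \code{"no_signal"},
#'   \code{"short_mature"} when applicable).
#' @examples
#' segmentPrecursor("MKTLVLVAVLGLALAEDAESEEARIFECVFSCDIEKEGKPCKPKG")
#' @export
segmentPrecursor <- function(protein, orf_id = NA_character_,
                             core_threshold = 1.6) {
  .checkAaString(protein, "protein", allow_x = TRUE)
  flags <- character(0)
  if (nchar(protein) < 25L || substr(protein, 1, 1) != "M") {
    sig <- list(position = NA_integer_, score = NA_real_, has_signal = FALSE)
  } else {
    sig <- predictSignalCleavage(protein, core_threshold = core_threshold)
  }
  if (!sig$has_signal) {
    mature <- protein
    signal <- ""
    prop <- ""
    rule <- "no_signal"
    flags <- c(flags, "no_signal")
  } else {
    signal <- substr(protein, 1L, sig$position)
    post <- substr(protein, sig$position + 1L, nchar(protein))
    pq <- predictPropeptideCleavage(post)
    prop <- substr(post, 1L, pq$offset)
    mature <- substr(post, pq$offset + 1L, nchar(post))
    rule <- pq$rule
  }
  if (nchar(mature) < 10L) flags <- c(flags, "short_mature")
  stopifnot(identical(paste0(signal, prop, mature), protein))
  list(orf_id = orf_id, signal = signal, propeptide = prop, mature = mature,
       signal_score = sig$score, cleavage_rule = rule, flags = flags)
}

#' Segment many ORFs at once
#'
#' @param proteins Named character vector (or DataFrame from
#'   \code{\link{transcriptOrfs}} with \code{protein}/\code{orf_id}
#'   columns) of ORF proteins.
#' @param core_threshold Passed to \code{\link{predictSignalCleavage}}.
#' @return \link[S4Vectors]{DataFrame} with one row per ORF: \code{orf_id},
#'   \code{signal}, \code{propeptide}, \code{mature}, \code{signal_score},
#'   \code{cleavage_rule}, \code{flags} (comma-collapsed).
#' @export
segmentPrecursors <- function(proteins, core_threshold = 1.6) {
  if (is(proteins, "DataFrame") || is.data.frame(proteins)) {
    ids <- proteins$orf_id
    proteins <- stats::setNames(proteins$protein, ids)
  }
  ids <- if (is.null(names(proteins))) as.character(seq_along(proteins))
         else names(proteins)
  res <- lapply(seq_along(proteins), function(i)
    segmentPrecursor(proteins[[i]], orf_id = ids[i],
                     core_threshold = core_threshold))
  S4Vectors::DataFrame(
    orf_id = vapply(res, `[[`, character(1), "orf_id"),
    signal = vapply(res, `[[`, character(1), "signal"),
    propeptide = vapply(res, `[[`, character(1), "propeptide"),
    mature = vapply(res, `[[`, character(1), "mature"),
    signal_score = vapply(res, `[[`, numeric(1), "signal_score"),
    cleavage_rule = vapply(res, `[[`, character(1), "cleavage_rule"),
    flags = vapply(res, function(r) paste(r$flags, collapse = ","), character(1)))
}
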