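# Theoretical peptide masses, m/z, MALDI mass-list matching, and
# amide/acid pair detection.

#' ModificationSet class
#'
#' A set of post-translational / sample-preparation modifications applied
#' to a peptide when computing its theoretical mass: disulfide bonds
#' (-2 H each), carbamidomethylated cysteines (+57.02146 Da each),
#' C-terminal amidation (-0.98402 Da) and methionine oxidation
#' (+15.99491 Da each). A cysteine can be engaged in a disulfide or
#' carbamidomethylated, never both.
#'
#' @slot disulfides Number of disulfide bonds.
#' @slot carbamidomethylCys Number of carbamidomethylated cysteines.
#' @slot cTerminalAmide Logical, C-terminal amide instead of free acid.
#' @slot metOxidation Number of oxidized methionines.
#' @exportClass ModificationSet
setClass("ModificationSet",
  representation(disulfides = "integer", carbamidomethylCys = "integer",
                 cTerminalAmide = "logical", metOxidation = "integer"),
  prototype(disulfides = 0L, carbamidomethylCys = 0L,
            cTerminalAmide = FALSE, metOxidation = 0L))

setValidity("ModificationSet", function(object) {
  msg <- character(0)
  if (object@disulfides < 0L || object@carbamidomethylCys < 0L ||
      object@metOxidation < 0L)
    msg <- c(msg, "modification counts must be >= 0")
  if (length(object@cTerminalAmide) != 1L || is.na(object@cTerminalAmide))
    msg <- c(msg, "cTerminalAmide must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a ModificationSet
#'
#' @param disulfides Number of disulfide bonds.
#' @param carbamidomethyl Number of carbamidomethylated cysteines.
#' @param c_terminal_amide Logical.
#' @param met_oxidation Number of oxidized methionines.
#' @return A \linkS4class{ModificationSet}.
#' @examples
#' modificationSet(disulfides = 3)
#' @export
modificationSet <- function(disulfides = 0, carbamidomethyl = 0,
                            c_terminal_amide = FALSE, met_oxidation = 0) {
  new("ModificationSet", disulfides = as.integer(disulfides),
      carbamidomethylCys = as.integer(carbamidomethyl),
      cTerminalAmide = c_terminal_amide,
      metOxidation = as.integer(met_oxidation))
}

setMethod("show", "ModificationSet", function(object) {
  cat("ModificationSet:", object@disulfides, "S-S,",
      object@carbamidomethylCys, "CAM-C,",
      object@metOxidation, "Mox,",
      if (object@cTerminalAmide) "C-terminal amide" else "free acid", "\n")
})

#' Fully-oxidized modification set for a peptide
#'
#' "All cysteines oxidized" means floor(n_cys / 2) disulfide bonds; an odd
#' cysteine count leaves one free cysteine, which is flagged.
#'
#' @param seq Peptide sequence.
#' @param c_terminal_amide Logical, add C-terminal amidation.
#' @return List with \code{mods} (\linkS4class{ModificationSet}) and
#'   \code{free_cys} (0 or 1).
#' @export
oxidizedModificationSet <- function(seq, c_terminal_amide = FALSE) {
  nc <- lengths(regmatches(seq, gregexpr("C", seq, fixed = TRUE)))
  list(mods = modificationSet(disulfides = nc %/% 2L,
                              c_terminal_amide = c_terminal_amide),
       free_cys = as.integer(nc %% 2L))
}

#' Theoretical peptide mass
#'
#' Sum of residue masses plus water plus modification deltas.
#' Monoisotopic by default; average-mass mode uses average residue/water
#' masses with the same (monoisotopic) modification deltas.
#'
#' @param seq Peptide string over the 20 standard residues (\code{X} is an
#'   error: an unknown residue has no mass).
#' @param mods A \linkS4class{ModificationSet}.
#' @param mode \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Neutral mass in Da.
#' @examples
#' peptideMass("G")  # 75.03203
#' @export
peptideMass <- function(seq, mods = modificationSet(),
                        mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  .checkAaString(seq, "seq", allow_x = FALSE)
  validObject(mods)
  aa <- strsplit(seq, "")[[1]]
  n_cys <- sum(aa == "C")
  n_met <- sum(aa == "M")
  if (mods@disulfides > n_cys %/% 2L)
    stop("more disulfides than floor(n_cys/2)")
  if (2L * mods@disulfides + mods@carbamidomethylCys > n_cys)
    stop("disulfide-bonded plus carbamidomethylated cysteines exceed cysteine count")
  if (mods@metOxidation > n_met)
    stop("more oxidized methionines than methionines")
  k <- massConstants()
  tab <- if (mode == "monoisotopic") .MONO_RESIDUE else .AVG_RESIDUE
  water <- if (mode == "monoisotopic") k[["water"]] else k[["water_avg"]]
  sum(tab[aa]) + water +
    mods@disulfides * k[["disulfide"]] +
    mods@carbamidomethylCys * k[["carbamidomethyl"]] +
    mods@metOxidation * k[["met_oxidation"]] +
    if (mods@cTerminalAmide) k[["c_term_amide"]] else 0
}

#' m/z of a neutral mass at charge z
#'
#' @param neutral_mass Neutral mass in Da (> 0).
#' @param z Positive integer charge.
#' @return (M + z * 1.007276) / z.
#' @examples
#' mz(1545.683, 2)  # 773.849
#' @export
mz <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != as.integer(z))) stop("z must be a positive integer")
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0")
  (neutral_mass + z * massConstants()[["proton"]]) / z
}

#' Match theoretical peptide masses against observed MALDI masses
#'
#' Computes the theoretical mass of every (peptide, modification set)
#' candidate and reports every combination within \code{tol} Da of an
#' observed neutral mass, sorted by absolute mass error.
#'
#' @param candidates Named list: for each peptide sequence, a list of
#'   \linkS4class{ModificationSet} objects to consider. A character vector
#'   of sequences is accepted (each gets its fully-oxidized acid and amide
#'   forms).
#' @param observed data.frame with columns \code{fraction_id},
#'   \code{neutral_mass} (Da) and optionally \code{intensity}.
#' @param tol Mass tolerance in Da (default 0.5, MALDI MS1).
#' @return \link[S4Vectors]{DataFrame} with columns \code{peptide},
#'   \code{mod_label}, \code{fraction_id}, \code{observed},
#'   \code{theoretical}, \code{delta}, sorted by \code{abs(delta)}.
#' @export
matchMasses <- function(candidates, observed, tol = 0.5) {
  if (tol <= 0) stop("tol must be > 0")
  if (is.character(candidates)) {
    seqs <- candidates
    candidates <- lapply(seqs, function(s) {
      list(oxidized = oxidizedModificationSet(s)$mods,
           oxidized_amide = oxidizedModificationSet(s, TRUE)$mods)
    })
    names(candidates) <- seqs
  }
  rows <- list()
  for (pep in names(candidates)) {
    mlist <- candidates[[pep]]
    labels <- if (is.null(names(mlist))) as.character(seq_along(mlist))
              else names(mlist)
    for (j in seq_along(mlist)) {
      theo <- peptideMass(pep, mlist[[j]])
      d <- observed$neutral_mass - theo
      hit <- which(abs(d) <= tol)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, mod_label = labels[j],
          fraction_id = as.character(observed$fraction_id[h]),
          observed = observed$neutral_mass[h], theoretical = theo,
          delta = d[h], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(peptide = character(0), mod_label = character(0),
                                fraction_id = character(0), observed = numeric(0),
                                theoretical = numeric(0), delta = numeric(0)))
  df <- do.call(rbind, rows)
  df <- df[order(abs(df$delta)), , drop = FALSE]
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Detect C-terminal amide / free-acid mass pairs
#'
#' Scans a list of observed neutral masses (across fractions) for pairs
#' whose difference matches the amidation delta: the amide form is
#' 0.98402 Da lighter than the acid form, which MALDI operators read as
#' "approximately 1 Da". Detection is symmetric and order-independent.
#'
#' @param observed data.frame with \code{fraction_id} and
#'   \code{neutral_mass} columns, or a numeric vector of masses.
#' @param pair_tol Tolerance in Da on \code{(heavy - light) - 0.98402}
#'   (default 0.05).
#' @return \link[S4Vectors]{DataFrame} with columns \code{heavy},
#'   \code{light}, \code{heavy_fraction}, \code{light_fraction},
#'   \code{delta} (raw heavy - light) and \code{rounded_delta} (nearest
#'   integer Da).
#' @examples
#' detectAmidationPairs(c(3810.60, 3809.61))
#' @export
detectAmidationPairs <- function(observed, pair_tol = 0.05) {
  if (pair_tol <= 0) stop("pair_tol must be > 0")
  if (is.numeric(observed))
    observed <- data.frame(
      fraction_id = rep(NA_character_, length(observed)),
      neutral_mass = observed)
  m <- observed$neutral_mass
  fr <- as.character(observed$fraction_id)
  amide_delta <- -massConstants()[["c_term_amide"]]
  rows <- list()
  n <- length(m)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      heavy <- max(m[i], m[j]); light <- min(m[i], m[j])
      hf <- if (m[i] >= m[j]) fr[i] else fr[j]
      lf <- if (m[i] >= m[j]) fr[j] else fr[i]
      d <- heavy - light
      if (abs(d - amide_delta) <= pair_tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          heavy = heavy, light = light, heavy_fraction = hf,
          light_fraction = lf, delta = d, rounded_delta = round(d),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(heavy = numeric(0), light = numeric(0),
                                heavy_fraction = character(0),
                                light_fraction = character(0),
                                delta = numeric(0), rounded_delta = numeric(0)))
  S4Vectors::DataFrame(do.call(rbind, rows))
}
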