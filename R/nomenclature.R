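# Rational toxin nomenclature:
#   <activity prefix>-<family>-<species abbrev><paralog><isoform>[_<variant>]
# e.g. "U29-theraphositoxin-Pv1b_1" or an omega-prefixed CaV modulator name.
# The activity prefix is a Greek letter for a known channel activity
# (omega CaV, mu/beta NaV, kappa KV) or "U" plus an index for
# unknown activity.

.ACTIVITY_PREFIX <- c(cav_modulator = "\u03c9", nav = "\u03bc",
                      nav_beta = "\u03b2", kv = "\u03ba")

#' ToxinName class
#'
#' Structured rational toxin name.
#'
#' @slot activityPrefix Activity prefix (Greek letter, or \code{"U<idx>"}).
#' @slot family Toxin family string, e.g. \code{"theraphotoxin"}.
#' @slot speciesAbbrev 2-3 letter species abbreviation (\code{"Pv"}).
#' @slot paralog Positive integer paralog number.
#' @slot isoform Single lowercase isoform letter.
#' @slot variant Optional positive integer variant (\code{NA} when
#'   absent).
#' @exportClass ToxinName
setClass("ToxinName",
  representation(activityPrefix = "character", family = "character",
                 speciesAbbrev = "character", paralog = "integer",
                 isoform = "character", variant = "integer"),
  prototype(variant = NA_integer_))

setValidity("ToxinName", function(object) {
  msg <- character(0)
  if (!grepl("^(U[0-9]+|[^-0-9]+)$", object@activityPrefix))
    msg <- c(msg, "malformed activity prefix")
  if (!grepl("^[A-Za-z]+$", object@family))
    msg <- c(msg, "family must be alphabetic")
  if (!grepl("^[A-Z][a-z]{1,2}$", object@speciesAbbrev))
    msg <- c(msg, "species abbreviation must be 2-3 letters, capitalized")
  if (is.na(object@paralog) || object@paralog < 1L)
    msg <- c(msg, "paralog must be a positive integer")
  if (!grepl("^[a-z]$", object@isoform))
    msg <- c(msg, "isoform must be a single lowercase letter")
  if (!is.na(object@variant) && object@variant < 1L)
    msg <- c(msg, "variant must be a positive integer when present")
  if (length(msg)) msg else TRUE
})

#' Render a ToxinName as its string form
#'
#' @param x A \linkS4class{ToxinName}.
#' @return The rendered name string.
#' @export
renderName <- function(x) {
  stopifnot(is(x, "ToxinName"))
  paste0(x@activityPrefix, "-", x@family, "-", x@speciesAbbrev,
         x@paralog, x@isoform,
         if (!is.na(x@variant)) paste0("_", x@variant) else "")
}

setMethod("show", "ToxinName", function(object) {
  cat("ToxinName:", renderName(object), "\n")
})

#' Assign a rational toxin name
#'
#' The species abbreviation is the genus initial (upper case) plus the
#' species initial (lower case); longer abbreviations can be forced with
#' \code{abbrev}. Unknown activity renders as \code{U} plus
#' \code{unknown_index}.
#'
#' @param activity One of \code{"cav_modulator"} (omega),
#'   \code{"nav"} (mu), \code{"nav_beta"} (beta),
#'   \code{"kv"} (kappa) or \code{"unknown"}.
#' @param family Family string (default \code{"theraphotoxin"}).
#' @param genus,species Binomial parts, non-empty.
#' @param paralog Positive integer.
#' @param isoform Lowercase letter.
#' @param variant Optional positive integer.
#' @param unknown_index U-number used when \code{activity = "unknown"}.
#' @param abbrev Optional explicit species abbreviation (2-3 letters)
#'   overriding the initials rule.
#' @return A \linkS4class{ToxinName}.
#' @examples
#' renderName(assignToxinName("unknown", "theraphositoxin",
#'   "Pamphobeteus", "verdolaga", 1, "b", 1, unknown_index = 29))
#' @export
assignToxinName <- function(activity, family = "theraphotoxin", genus,
                            species, paralog, isoform, variant = NA,
                            unknown_index = NA, abbrev = NULL) {
  if (!activity %in% c(names(.ACTIVITY_PREFIX), "unknown"))
    stop("invalid activity: ", activity)
  if (!nzchar(genus) || !nzchar(species)) stop("genus/species must be non-empty")
  prefix <- if (activity == "unknown") {
    if (is.na(unknown_index)) stop("unknown activity requires unknown_index")
    paste0("U", as.integer(unknown_index))
  } else .ACTIVITY_PREFIX[[activity]]
  if (is.null(abbrev))
    abbrev <- paste0(toupper(substr(genus, 1, 1)),
                     tolower(substr(species, 1, 1)))
  new("ToxinName", activityPrefix = prefix, family = family,
      speciesAbbrev = abbrev, paralog = as.integer(paralog),
      isoform = as.character(isoform),
      variant = if (is.na(variant)) NA_integer_ else as.integer(variant))
}

#' Parse a rational toxin name
#'
#' Inverse of \code{\link{renderName}}; the round trip is exact.
#'
#' @param s Name string.
#' @return A \linkS4class{ToxinName}.
#' @examples
#' parseToxinName("\u03c9-theraphotoxin-Asp1a")
#' @export
parseToxinName <- function(s) {
  re <- "^(U[0-9]+|[^-0-9]+)-([A-Za-z]+)-([A-Z][a-z]{1,2})([0-9]+)([a-z])(?:_([0-9]+))?$"
  m <- regmatches(s, regexec(re, s, perl = TRUE))[[1]]
  if (!length(m)) {
    # locate the first structural failure for the error message
    dash <- regexpr("-", s, fixed = TRUE)
    pos <- if (dash < 0) nchar(s) else as.integer(dash)
    stop("cannot parse toxin name '", s, "' (structure breaks near position ",
         pos, ")")
  }
  new("ToxinName", activityPrefix = m[2], family = m[3], speciesAbbrev = m[4],
      paralog = as.integer(m[5]), isoform = m[6],
      variant = if (m[7] == "") NA_integer_ else as.integer(m[7]))
}

#' Allocate the next free U-number in a catalogue
#'
#' @param existing Character vector of already-used rendered names.
#' @return Smallest positive integer not used as a U-number in
#'   \code{existing}.
#' @export
nextUnknownIndex <- function(existing) {
  used <- suppressWarnings(as.integer(sub("^U([0-9]+)-.*$", "\\1",
                                          grep("^U[0-9]+-", existing, value = TRUE))))
  used <- used[!is.na(used)]
  cand <- 1L
  while (cand %in% used) cand <- cand + 1L
  cand
}
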