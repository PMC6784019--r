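# Pipeline orchestration: transcripts + MS observations -> toxin catalogue.

#' ToxinCatalogue class
#'
#' The assembled result of a pipeline run: one record per classified
#' cysteine-rich mature peptide with its precursor segmentation,
#' framework, superfamily, mass and fragment evidence, coverage,
#' abundance and rational name, plus the superfamily summary table.
#'
#' @slot records \link[S4Vectors]{DataFrame}, one row per toxin.
#' @slot summary data.frame, one row per superfamily (name, pattern,
#'   cysteine count, observed length range, member count).
#' @slot massMatches \link[S4Vectors]{DataFrame} of MALDI mass matches.
#' @slot fragmentMatches \link[S4Vectors]{DataFrame} of MS/MS fragment
#'   matches.
#' @slot config List of thresholds the run used.
#' @exportClass ToxinCatalogue
setClass("ToxinCatalogue",
  representation(records = "DataFrame", summary = "data.frame",
                 massMatches = "DataFrame", fragmentMatches = "DataFrame",
                 config = "list"))

setValidity("ToxinCatalogue", function(object) {
  msg <- character(0)
  if (nrow(object@records)) {
    if (anyDuplicated(object@records$name))
      msg <- c(msg, "toxin names must be unique in a catalogue")
    counts <- table(object@records$superfamily)
    for (sf in rownames(counts)) {
      row <- object@summary[object@summary$superfamily == sf, , drop = FALSE]
      if (nrow(row) != 1L || row$members != counts[[sf]]) {
        msg <- c(msg, "summary member counts disagree with records")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn runPipeline Records accessor.
#' @export
setGeneric("toxinRecords", function(x) standardGeneric("toxinRecords"))
setMethod("toxinRecords", "ToxinCatalogue", function(x) x@records)

#' @describeIn runPipeline Superfamily summary accessor.
#' @export
setGeneric("superfamilySummary", function(x) standardGeneric("superfamilySummary"))
setMethod("superfamilySummary", "ToxinCatalogue", function(x) x@summary)

#' @describeIn runPipeline MALDI mass-match accessor.
#' @export
setGeneric("massMatches", function(x) standardGeneric("massMatches"))
setMethod("massMatches", "ToxinCatalogue", function(x) x@massMatches)

#' @describeIn runPipeline Fragment-match accessor.
#' @export
setGeneric("fragmentMatches", function(x) standardGeneric("fragmentMatches"))
setMethod("fragmentMatches", "ToxinCatalogue", function(x) x@fragmentMatches)

setMethod("show", "ToxinCatalogue", function(object) {
  cat("ToxinCatalogue with", nrow(object@records), "records in",
      nrow(object@summary), "superfamilies\n")
  if (nrow(object@summary)) print(object@summary, row.names = FALSE)
})

#' Completeness percentage
#'
#' Percentage of conserved single-copy orthologs recovered, to one
#' decimal.
#'
#' @param complete Number recovered (0 <= complete <= total).
#' @param total Total benchmarked (> 0).
#' @return round(100 * complete / total, 1).
#' @examples
#' completenessPercent(255, 303)  # 84.2
#' @export
completenessPercent <- function(complete, total) {
  if (total <= 0) stop("total must be > 0")
  if (complete < 0 || complete > total)
    stop("complete must be between 0 and total")
  round(100 * complete / total, 1)
}

#' Summarize a record table by superfamily
#'
#' One row per superfamily: canonical pattern, cysteine count, observed
#' mature-length range, member count. Scheme superfamilies sort first
#' (SF1..SFn), then novel patterns in first-occurrence order named
#' novel-1, novel-2, ...
#'
#' @param records DataFrame/data.frame with \code{superfamily},
#'   \code{canonical}, \code{n_cys} and \code{mature} columns.
#' @return data.frame summary.
#' @export
summarizeSuperfamilies <- function(records) {
  if (!nrow(records))
    return(data.frame(superfamily = character(0), canonical = character(0),
                      n_cys = integer(0), len_min = integer(0),
                      len_max = integer(0), members = integer(0),
                      stringsAsFactors = FALSE))
  sf <- records$superfamily
  lens <- nchar(records$mature)
  keys <- unique(sf)
  scheme <- sort(grep("^SF[0-9]+$", keys, value = TRUE))
  novel <- keys[!keys %in% scheme]
  keys <- c(scheme, novel)
  rows <- lapply(keys, function(k) {
    sel <- sf == k
    data.frame(superfamily = k,
               canonical = records$canonical[sel][1],
               n_cys = records$n_cys[sel][1],
               len_min = min(lens[sel]), len_max = max(lens[sel]),
               members = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# allocate catalogue names: per superfamily one U-number, isoform letters
# for distinct matures, variant suffixes for identical matures
.catalogueNames <- function(records, genus, species, family) {
  names_out <- character(nrow(records))
  used <- character(0)
  for (sf in unique(records$superfamily)) {
    sel <- which(records$superfamily == sf)
    u <- nextUnknownIndex(used)
    distinct <- unique(records$mature[sel])
    for (i in sel) {
      iso_idx <- match(records$mature[i], distinct)
      iso <- letters[((iso_idx - 1L) %% 26L) + 1L]
      variant <- sum(records$mature[sel][seq_len(which(sel == i))] ==
                       records$mature[i])
      nm <- assignToxinName("unknown", family = family, genus = genus,
                            species = species, paralog = 1L, isoform = iso,
                            variant = variant, unknown_index = u)
      names_out[i] <- renderName(nm)
      used <- c(used, names_out[i])
    }
  }
  names_out
}

#' Segment every transcript into its best precursor candidate
#'
#' Extracts all ORFs of every transcript, segments each, and keeps one
#' precursor per transcript: the candidate that looks most like a secreted
#' toxin precursor. Candidates are ranked by presence of a signal peptide,
#' then a processing-quadruplet propeptide cleavage, then mature cysteine
#' count, then ORF length (a transcript's coding ORF is not always its
#' longest: random open stretches on the opposite strand can be longer).
#'
#' @param transcripts \link[Biostrings]{DNAStringSet}.
#' @param min_orf_len Minimum ORF length in residues (default 40).
#' @param core_threshold Signal-peptide hydrophobicity threshold.
#' @return \link[S4Vectors]{DataFrame} as from
#'   \code{\link{segmentPrecursors}} plus a \code{transcript_id} column,
#'   one row per transcript with at least one ORF.
#' @export
segmentTranscripts <- function(transcripts, min_orf_len = 40L,
                               core_threshold = 1.6) {
  orfs <- transcriptOrfs(transcripts, min_len = min_orf_len)
  if (!nrow(orfs)) {
    out <- segmentPrecursors(character(0))
    out$transcript_id <- character(0)
    return(out)
  }
  seg <- segmentPrecursors(orfs, core_threshold = core_threshold)
  seg$transcript_id <- orfs$transcript_id
  n_cys <- vapply(seg$mature, function(m)
    sum(strsplit(m, "")[[1]] == "C"), integer(1))
  rank <- order(seg$transcript_id,
                seg$cleavage_rule == "no_signal",      # signal first
                seg$cleavage_rule != "PQM",            # then PQM
                -n_cys,                                # then cysteine-rich
                -nchar(orfs$protein))                  # then longest
  seg <- seg[rank, , drop = FALSE]
  seg[!duplicated(seg$transcript_id), , drop = FALSE]
}

#' Run the full proteo-transcriptomic pipeline
#'
#' Reads transcripts, segments each into its best precursor candidate
#' (\code{\link{segmentTranscripts}}), keeps cysteine-rich mature
#' peptides, classifies their
#' frameworks, matches theoretical masses (fully-oxidized acid and amide
#' forms) against MALDI observations, maps MS/MS fragments by local
#' alignment with region labels and mature-peptide coverage, and assigns
#' rational names. Deterministic given inputs and configuration.
#'
#' @param transcripts \link[Biostrings]{DNAStringSet} or FASTA path.
#' @param fragments Optional data.frame (\code{id}, \code{sequence}, ...)
#'   or TSV path of de novo MS/MS fragments.
#' @param masses Optional data.frame (\code{fraction_id},
#'   \code{neutral_mass}) or CSV path of MALDI neutral masses.
#' @param min_orf_len Minimum ORF length, residues (default 40).
#' @param min_cysteines Minimum cysteines for a mature peptide to enter
#'   the catalogue (default 5, the smallest cysteine count in the shipped
#'   superfamily scheme).
#' @param mass_tol MALDI match tolerance, Da (default 0.5).
#' @param pair_tol Amide/acid pair tolerance, Da (default 0.05).
#' @param min_align_score Minimum fragment alignment score (default 20).
#' @param genus,species,family Naming configuration.
#' @param defs Superfamily definitions.
#' @param scheme Alignment \code{\link{scoringScheme}}.
#' @return A \linkS4class{ToxinCatalogue}.
#' @export
runPipeline <- function(transcripts, fragments = NULL, masses = NULL,
                        min_orf_len = 40L, min_cysteines = 5L,
                        mass_tol = 0.5, pair_tol = 0.05,
                        min_align_score = 20,
                        genus = "Pamphobeteus", species = "verdolaga",
                        family = "theraphotoxin",
                        defs = superfamilyDefinitions(),
                        scheme = scoringScheme()) {
  if (is.character(transcripts)) transcripts <- readTranscriptFasta(transcripts)
  if (is.character(fragments))
    fragments <- utils::read.delim(fragments, stringsAsFactors = FALSE)
  if (is.character(masses))
    masses <- utils::read.csv(masses, stringsAsFactors = FALSE)
  abund <- S4Vectors::mcols(transcripts)$abundance
  if (is.null(abund)) abund <- rep(NA_real_, length(transcripts))
  names(abund) <- names(transcripts)

  prec <- segmentTranscripts(transcripts, min_orf_len = min_orf_len)
  if (!nrow(prec))
    return(new("ToxinCatalogue", records = .emptyRecords(),
               summary = summarizeSuperfamilies(.emptyRecords()),
               massMatches = matchMasses(character(0),
                 data.frame(fraction_id = character(0), neutral_mass = numeric(0))),
               fragmentMatches = .emptyFragmentMatches(),
               config = list(min_orf_len = min_orf_len)))

  fws <- lapply(prec$mature, extractFramework)
  n_cys <- vapply(fws, nCysteines, integer(1))
  canon <- vapply(fws, canonicalPattern, character(1))
  keep <- n_cys >= min_cysteines
  records <- S4Vectors::DataFrame(
    transcript_id = prec$transcript_id[keep],
    orf_id = prec$orf_id[keep],
    signal = prec$signal[keep], propeptide = prec$propeptide[keep],
    mature = prec$mature[keep], cleavage_rule = prec$cleavage_rule[keep],
    canonical = canon[keep], n_cys = n_cys[keep])
  cls <- lapply(seq_len(nrow(records)), function(i)
    classifySuperfamily(records$canonical[i], defs,
                        mature_len = nchar(records$mature[i])))
  records$superfamily <- vapply(cls, `[[`, character(1), "superfamily")
  records$length_warning <- vapply(cls, `[[`, logical(1), "length_warning")
  records$abundance <- unname(abund[records$transcript_id])

  # MALDI evidence
  if (!is.null(masses) && nrow(records)) {
    mm <- matchMasses(unique(records$mature), masses, tol = mass_tol)
    pairs <- detectAmidationPairs(masses, pair_tol = pair_tol)
  } else {
    mm <- matchMasses(character(0),
      data.frame(fraction_id = character(0), neutral_mass = numeric(0)))
    pairs <- detectAmidationPairs(numeric(0), pair_tol = pair_tol)
  }
  records$n_mass_matches <- if (nrow(mm)) vapply(records$mature, function(m)
    sum(mm$peptide == m), integer(1)) else integer(nrow(records))

  # fragment evidence and coverage
  if (!is.null(fragments) && nrow(fragments) && nrow(records)) {
    db <- records[, c("orf_id", "signal", "propeptide", "mature")]
    fm <- searchFragments(fragments, db, scheme = scheme,
                          min_score = min_align_score)
    cov <- vapply(seq_len(nrow(records)), function(i) {
      sel <- fm$target_id == records$orf_id[i]
      if (!any(sel)) return(0)
      off <- nchar(records$signal[i]) + nchar(records$propeptide[i])
      spans <- lapply(which(sel), function(k)
        c(fm$target_start[k] - off, fm$target_end[k] - off))
      computeCoverage(spans, nchar(records$mature[i]))
    }, numeric(1))
    records$coverage <- cov
  } else {
    fm <- .emptyFragmentMatches()
    records$coverage <- numeric(nrow(records))
  }

  if (nrow(records))
    records$name <- .catalogueNames(records, genus, species, family)

  summary <- summarizeSuperfamilies(records)
  out <- new("ToxinCatalogue", records = records, summary = summary,
             massMatches = mm, fragmentMatches = fm,
             config = list(min_orf_len = min_orf_len,
                           min_cysteines = min_cysteines,
                           mass_tol = mass_tol, pair_tol = pair_tol,
                           min_align_score = min_align_score,
                           genus = genus, species = species,
                           family = family))
  metadata0 <- list(amidation_pairs = pairs)
  S4Vectors::metadata(out@records) <- metadata0
  out
}

.emptyRecords <- function() {
  S4Vectors::DataFrame(
    transcript_id = character(0), orf_id = character(0),
    signal = character(0), propeptide = character(0), mature = character(0),
    cleavage_rule = character(0), canonical = character(0),
    n_cys = integer(0), superfamily = character(0),
    length_warning = logical(0), abundance = numeric(0),
    n_mass_matches = integer(0), coverage = numeric(0), name = character(0))
}

.emptyFragmentMatches <- function() {
  S4Vectors::DataFrame(fragment_id = character(0), target_id = character(0),
                       score = numeric(0), identity = numeric(0),
                       target_start = integer(0), target_end = integer(0),
                       region = character(0))
}

#' Write catalogue outputs
#'
#' Writes catalogue.tsv, superfamilies.tsv, matches.tsv, catalogue.fasta
#' (mature peptides named by their rational names) and manifest.json
#' (configuration and record counts). Output is byte-identical across
#' reruns on the same inputs.
#'
#' @param catalogue A \linkS4class{ToxinCatalogue}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCatalogue <- function(catalogue, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("catalogue.tsv", "superfamilies.tsv",
                            "matches.tsv", "catalogue.fasta",
                            "manifest.json"))
  rec <- as.data.frame(toxinRecords(catalogue))
  utils::write.table(rec, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(superfamilySummary(catalogue), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fragmentMatches(catalogue)), paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(rec)) {
    fa <- Biostrings::AAStringSet(rec$mature)
    names(fa) <- rec$name
    Biostrings::writeXStringSet(fa, paths[4])
  } else writeLines(character(0), paths[4])
  jsonlite::write_json(
    list(config = catalogue@config,
         n_records = nrow(rec),
         n_superfamilies = nrow(superfamilySummary(catalogue))),
    paths[5], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
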