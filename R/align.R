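# Smith-Waterman mapping of de novo MS/MS fragment sequences onto
# translated transcripts and mature peptides.
#
# Two conventions specific to de novo MS data are baked into the default
# scoring: isoleucine and leucine are isobaric and therefore treated as
# identical, and an 'X' (residue called but not identified) aligns to any
# residue at score 0 and is excluded from the identity denominator.

#' Build an alignment scoring scheme
#'
#' BLOSUM62 substitution scores with affine gaps. Opening a gap costs
#' \code{-gap_open} and every gapped position a further \code{-gap_extend}
#' (so a length-1 gap scores \code{gap_open + gap_extend}).
#'
#' @param matrix Substitution matrix name (only \code{"BLOSUM62"} shipped)
#'   or a symmetric numeric matrix with residue dimnames.
#' @param gap_open Gap opening score (negative, default -10).
#' @param gap_extend Gap extension score per position (negative, default
#'   -1).
#' @param il_equivalent Treat I and L as identical (default TRUE).
#' @param x_match_any 'X' aligns to anything at score 0 (default TRUE).
#' @return List of class \code{"ScoringScheme"} with the resolved
#'   substitution matrix and penalties.
#' @examples
#' s <- scoringScheme()
#' s$matrix["I", "L"]
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gap_open = -10,
                          gap_extend = -1, il_equivalent = TRUE,
                          x_match_any = TRUE) {
  if (gap_open >= 0 || gap_extend >= 0) stop("gap penalties must be negative")
  if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("unknown matrix: ", matrix)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  } else mat <- matrix
  if (!isSymmetric(unname(mat))) stop("substitution matrix must be symmetric")
  if (il_equivalent) {
    m <- min(mat["I", "I"], mat["L", "L"])
    mat["I", "L"] <- mat["L", "I"] <- m
  }
  if (x_match_any && "X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
                 il_equivalent = il_equivalent, x_match_any = x_match_any),
            class = "ScoringScheme")
}

# residue-pair identity under the scheme's conventions
.residuesMatch <- function(a, b, il_equivalent) {
  a == b | (il_equivalent & a %in% c("I", "L") & b %in% c("I", "L"))
}

#' Optimal local alignment of two peptide sequences
#'
#' Smith-Waterman local alignment under a \code{\link{scoringScheme}}.
#' Percent identity is computed over the aligned columns excluding any
#' column containing \code{X}; I/L count as identical under the default
#' scheme. Gap columns count in the denominator.
#'
#' @param query,target Non-empty amino-acid strings (\code{X} allowed).
#' @param scheme A \code{\link{scoringScheme}}.
#' @return List with \code{score}, \code{identity} (percent),
#'   \code{query_span} and \code{target_span} (0-based half-open),
#'   \code{aligned_query}, \code{aligned_target}.
#' @examples
#' localAlign("IFECVFSCDIEK", "IFECVFSCDIEKEGKPCKPK")$identity  # 100
#' @export
localAlign <- function(query, target, scheme = scoringScheme()) {
  .checkAaString(query, "query", allow_x = TRUE)
  .checkAaString(target, "target", allow_x = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  ap <- as.character(Biostrings::pattern(pa))
  at <- as.character(Biostrings::subject(pa))
  qa <- strsplit(ap, "")[[1]]
  ta <- strsplit(at, "")[[1]]
  keep <- qa != "X" & ta != "X"
  ident <- if (!any(keep)) 100 else {
    idc <- .residuesMatch(qa[keep], ta[keep], scheme$il_equivalent) &
      qa[keep] != "-" & ta[keep] != "-"
    100 * sum(idc) / sum(keep)
  }
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  list(score = Biostrings::score(pa),
       identity = ident,
       query_span = c(IRanges::start(p) - 1L, IRanges::end(p)),
       target_span = c(IRanges::start(s) - 1L, IRanges::end(s)),
       aligned_query = ap, aligned_target = at)
}

# vectorized local alignment of many queries against one target
.localAlignMany <- function(queries, target, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(target),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  ap <- as.character(Biostrings::pattern(pa))
  at <- as.character(Biostrings::subject(pa))
  ident <- vapply(seq_along(queries), function(i) {
    qa <- strsplit(ap[i], "")[[1]]
    ta <- strsplit(at[i], "")[[1]]
    keep <- qa != "X" & ta != "X"
    if (!any(keep)) return(100)
    idc <- .residuesMatch(qa[keep], ta[keep], scheme$il_equivalent) &
      qa[keep] != "-" & ta[keep] != "-"
    100 * sum(idc) / sum(keep)
  }, numeric(1))
  s <- Biostrings::subject(pa)
  data.frame(score = Biostrings::score(pa), identity = ident,
             target_start = IRanges::start(s) - 1L,
             target_end = IRanges::end(s))
}

# region of a target span given precursor segment lengths
.spanRegion <- function(span, sig_len, pro_len, mat_len) {
  if (is.na(sig_len)) return(NA_character_)
  bounds <- cumsum(c(sig_len, pro_len, mat_len))
  s <- span[1]; e <- span[2]
  if (e <= bounds[1]) return("signal")
  if (s >= bounds[1] && e <= bounds[2]) return("propeptide")
  if (s >= bounds[2]) return("mature")
  "spanning"
}

#' Search MS/MS fragments against a protein database
#'
#' Exhaustive local alignment of every fragment against every database
#' entry; hits with score >= \code{min_score} are returned best-first per
#' fragment (ties broken by database order, then id). When the database is
#' a precursor table the matched region (signal / propeptide / mature /
#' spanning) is labelled from the segmentation.
#'
#' @param frags data.frame with columns \code{id} and \code{sequence}
#'   (optionally \code{mz}, \code{z}, \code{flank_n}, \code{flank_c}), or
#'   a named character vector of sequences.
#' @param db Named character vector of protein sequences, or a precursor
#'   \link[S4Vectors]{DataFrame} from \code{\link{segmentPrecursors}}
#'   (full protein reconstituted as signal+propeptide+mature).
#' @param scheme A \code{\link{scoringScheme}}.
#' @param min_score Minimum alignment score to report (default 0 keeps
#'   any positive-scoring local alignment).
#' @return \link[S4Vectors]{DataFrame} with columns \code{fragment_id},
#'   \code{target_id}, \code{score}, \code{identity}, \code{target_start},
#'   \code{target_end}, \code{region}.
#' @export
searchFragments <- function(frags, db, scheme = scoringScheme(),
                            min_score = 0) {
  if (is.character(frags))
    frags <- data.frame(id = if (is.null(names(frags)))
      as.character(seq_along(frags)) else names(frags),
      sequence = unname(frags), stringsAsFactors = FALSE)
  precursor_db <- (is(db, "DataFrame") || is.data.frame(db)) &&
    all(c("signal", "propeptide", "mature") %in% colnames(db))
  if (precursor_db) {
    ids <- db$orf_id
    seqs <- paste0(db$signal, db$propeptide, db$mature)
    sig_len <- nchar(db$signal); pro_len <- nchar(db$propeptide)
    mat_len <- nchar(db$mature)
  } else {
    seqs <- as.character(db)
    ids <- if (is.null(names(db))) as.character(seq_along(db)) else names(db)
    sig_len <- rep(NA_integer_, length(seqs))
    pro_len <- mat_len <- sig_len
  }
  if (!length(seqs)) stop("empty database")
  per_target <- lapply(seq_along(seqs), function(j) {
    al <- .localAlignMany(frags$sequence, seqs[j], scheme)
    al$fragment_id <- frags$id
    al$target_id <- ids[j]
    al$db_order <- j
    al$region <- vapply(seq_len(nrow(al)), function(k)
      .spanRegion(c(al$target_start[k], al$target_end[k]),
                  sig_len[j], pro_len[j], mat_len[j]), character(1))
    al[al$score >= min_score & al$score > 0, , drop = FALSE]
  })
  all_hits <- do.call(rbind, per_target)
  rows <- list()
  for (id in frags$id) {
    h <- all_hits[all_hits$fragment_id == id, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(-h$score, h$db_order, h$target_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      h[, c("fragment_id", "target_id", "score", "identity",
            "target_start", "target_end", "region", "db_order")]
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(fragment_id = character(0),
                                target_id = character(0), score = numeric(0),
                                identity = numeric(0), target_start = integer(0),
                                target_end = integer(0), region = character(0)))
  df <- do.call(rbind, rows)
  df$db_order <- NULL
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Mature-peptide coverage from fragment matches
#'
#' Percent of the mature peptide covered by the union of mature-region
#' match spans (spans given in mature-peptide coordinates, 0-based
#' half-open).
#'
#' @param spans List of length-2 integer vectors, or a two-column matrix /
#'   data.frame of \code{start}, \code{end} (0-based half-open).
#' @param mature_len Mature peptide length in residues (> 0).
#' @return Exact coverage percent in [0, 100].
#' @examples
#' computeCoverage(list(c(0, 21)), 32)  # 65.625, prints as 66%
#' @export
computeCoverage <- function(spans, mature_len) {
  if (mature_len <= 0) stop("mature_len must be > 0")
  if (is.matrix(spans) || is.data.frame(spans))
    spans <- lapply(seq_len(nrow(spans)), function(i) as.integer(spans[i, 1:2]))
  spans <- Filter(function(s) s[2] > s[1], spans)
  if (!length(spans)) return(0)
  st <- pmax(0L, vapply(spans, function(s) as.integer(s[1]), integer(1)))
  en <- pmin(as.integer(mature_len),
             vapply(spans, function(s) as.integer(s[2]), integer(1)))
  keep <- en > st
  if (!any(keep)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = st[keep] + 1L, end = en[keep]))
  100 * sum(IRanges::width(ir)) / mature_len
}
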