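#' Read assembled transcripts from FASTA
#'
#' Reads a (possibly line-wrapped) nucleotide FASTA of assembled transcripts.
#' Sequences are upper-cased, RNA \code{U} is converted to \code{T}, and the
#' alphabet is restricted to \code{A/C/G/T/N}; any other character is a parse
#' error naming the offending record. Record order is preserved and the
#' identifier is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} with an \code{abundance}
#'   metadata column (TPM units, \code{NA} when unknown).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c7142", "ATGAAA"), fa)
#' readTranscriptFasta(fa)
#' @export
readTranscriptFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA: ", path)
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(abundance = numeric(0))
    return(out)
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(raw))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("parse error in record '", ids[i], "' (record ", i, "): empty sequence")
    bad <- setdiff(strsplit(seqs[i], "")[[1]], c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("parse error in record '", ids[i], "' (record ", i,
           "): illegal character(s) ", paste(unique(bad), collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(abundance = rep(NA_real_, length(out)))
  out
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames: \code{+1..+3}
#' from the forward strand at offsets 0, 1, 2 and \code{-1..-3} from the
#' reverse complement at offsets 0, 1, 2. Trailing partial codons are
#' dropped, stop codons appear as \code{*}, and any codon containing
#' \code{N} translates to \code{X}.
#'
#' @param x A single nucleotide sequence (character or
#'   \link[Biostrings]{DNAString}), length >= 3.
#' @return Named character vector of the six translations
#'   (\code{"+1"} ... \code{"-3"}).
#' @examples
#' sixFrameTranslate("ATGAAA")[["+1"]]  # "MK"
#' @export
sixFrameTranslate <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (length(x) != 1L) stop("x must be a single sequence")
  x <- gsub("U", "T", toupper(x), fixed = TRUE)
  n <- nchar(x)
  if (n < 3L) stop("sequence shorter than 3 nt cannot be translated")
  fwd <- Biostrings::DNAString(x)
  rev <- Biostrings::reverseComplement(fwd)
  oneFrame <- function(s, off) {
    len <- length(s) - off
    len <- len - (len %% 3L)
    if (len < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + len),
                                       if.fuzzy.codon = "X"))
  }
  res <- c(vapply(0:2, function(o) oneFrame(fwd, o), character(1)),
           vapply(0:2, function(o) oneFrame(rev, o), character(1)))
  names(res) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  res
}

#' Extract open reading frames from six-frame translations
#'
#' Scans each frame translation for maximal ORFs: within every
#' stop-delimited segment the ORF runs from the first methionine to the
#' stop (or to the end of the frame for incomplete ORFs). ORFs may contain
#' \code{X} but never \code{*}. Results are sorted longest-first.
#'
#' Protein coordinates (\code{aa_start}, \code{aa_end}) are 0-based
#' half-open within the frame translation; \code{nt_start}/\code{nt_end}
#' are the corresponding 0-based half-open interval on the forward strand
#' of the transcript.
#'
#' @param frames Named character vector as returned by
#'   \code{\link{sixFrameTranslate}}.
#' @param min_len Minimum ORF length in residues (default 40).
#' @param transcript_id Identifier recorded in the output.
#' @param nt_len Nucleotide length of the source transcript (needed for
#'   \code{nt_start}/\code{nt_end}; defaults to \code{NA}).
#' @return A \link[S4Vectors]{DataFrame} with columns \code{transcript_id},
#'   \code{frame}, \code{aa_start}, \code{aa_end}, \code{nt_start},
#'   \code{nt_end}, \code{incomplete} (no stop codon seen) and
#'   \code{protein}.
#' @examples
#' extractOrfs(c("+1" = "MKKK*"), min_len = 3)
#' @export
extractOrfs <- function(frames, min_len = 40L, transcript_id = NA_character_,
                        nt_len = NA_integer_) {
  if (min_len < 1L) stop("min_len must be >= 1")
  rows <- list()
  for (fr in names(frames)) {
    prot <- frames[[fr]]
    if (is.na(prot) || nchar(prot) == 0L) next
    # stop-delimited segments with their 0-based offsets
    segs <- strsplit(prot, "*", fixed = TRUE)[[1]]
    offs <- c(0L, cumsum(nchar(segs) + 1L))
    n_seg <- length(segs)
    for (k in seq_len(n_seg)) {
      seg <- segs[k]
      m <- regexpr("M", seg, fixed = TRUE)
      if (m < 0L) next
      orf <- substr(seg, m, nchar(seg))
      if (nchar(orf) < min_len) next
      aa_start <- offs[k] + as.integer(m) - 1L
      aa_end <- aa_start + nchar(orf)
      # incomplete when the segment is the tail of the frame with no stop
      incomplete <- (k == n_seg) && !endsWith(prot, "*")
      nt <- .orfNtRange(fr, aa_start, aa_end, nt_len)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcript_id, frame = fr,
        aa_start = aa_start, aa_end = aa_end,
        nt_start = nt[1], nt_end = nt[2],
        incomplete = incomplete, protein = orf,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(S4Vectors::DataFrame(
      transcript_id = character(0), frame = character(0),
      aa_start = integer(0), aa_end = integer(0),
      nt_start = integer(0), nt_end = integer(0),
      incomplete = logical(0), protein = character(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-nchar(df$protein)), , drop = FALSE]
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

# Map frame-local protein coordinates back to a forward-strand nucleotide
# interval (0-based half-open). Reverse frames are measured from the 3' end.
.orfNtRange <- function(frame, aa_start, aa_end, nt_len) {
  if (is.na(nt_len)) return(c(NA_integer_, NA_integer_))
  off <- abs(as.integer(sub("^[+-]", "", frame))) - 1L
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (startsWith(frame, "+")) c(s, e) else c(nt_len - e, nt_len - s)
}

#' ORFs for every transcript in a set
#'
#' Convenience wrapper running \code{\link{sixFrameTranslate}} and
#' \code{\link{extractOrfs}} over a transcript set.
#'
#' @param transcripts A \link[Biostrings]{DNAStringSet} (named).
#' @param min_len Minimum ORF length in residues.
#' @return Combined \link[S4Vectors]{DataFrame} of ORFs with an added
#'   \code{orf_id} column (\code{<transcript>|<frame>|<aa_start>}).
#' @export
transcriptOrfs <- function(transcripts, min_len = 40L) {
  parts <- lapply(seq_along(transcripts), function(i) {
    if (nchar(as.character(transcripts[[i]])) < 3L) return(NULL)
    extractOrfs(sixFrameTranslate(transcripts[[i]]), min_len = min_len,
                transcript_id = names(transcripts)[i],
                nt_len = length(transcripts[[i]]))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(S4Vectors::DataFrame(
      transcript_id = character(0), frame = character(0),
      aa_start = integer(0), aa_end = integer(0),
      nt_start = integer(0), nt_end = integer(0),
      incomplete = logical(0), protein = character(0),
      orf_id = character(0)))
  out <- do.call(rbind, parts)
  out$orf_id <- paste(out$transcript_id, out$frame, out$aa_start, sep = "|")
  out
}
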