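# Domain-signature mini-language.
#
# Signatures are written the way cysteine-rich domain patterns are printed
# in the venomics literature, e.g. "X_n_CPX_6/8_CX_6_CX_5_CX_5_CCX_3/4_C"
# for the WAP four-disulfide core. Grammar (whitespace and underscores are
# ignored):
#   - a residue letter matches itself;
#   - X            one arbitrary residue;
#   - X5           exactly 5 arbitrary residues;
#   - X6/8         exactly 6 or exactly 8 arbitrary residues;
#   - Xn           any number (>= 0) of arbitrary residues;
#   - (P/R/A)      one residue from the alternation.

#' Parse a domain-signature pattern
#'
#' @param pattern Signature string in the mini-language above.
#' @return List of tokens, each a list with \code{type} (\code{"lit"},
#'   \code{"class"}, \code{"spacer"}, \code{"any"}) and, as applicable,
#'   \code{residue}, \code{residues} or \code{lengths}.
#' @examples
#' length(parseSignature("GX2RYSX(P/R/A)XC"))
#' @export
parseSignature <- function(pattern) {
  s <- gsub("[_[:space:]]", "", pattern)
  chars <- strsplit(s, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  perr <- function(i, what)
    stop("signature grammar error at position ", i, ": ", what)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      j <- i + 1L
      if (j <= n && chars[j] == "n") {
        toks[[length(toks) + 1L]] <- list(type = "any")
        i <- j + 1L
      } else if (j <= n && grepl("[0-9]", chars[j])) {
        lens <- integer(0)
        repeat {
          k <- j
          while (k <= n && grepl("[0-9]", chars[k])) k <- k + 1L
          lens <- c(lens, as.integer(paste(chars[j:(k - 1L)], collapse = "")))
          if (k <= n && chars[k] == "/") {
            j <- k + 1L
            if (j > n || !grepl("[0-9]", chars[j]))
              perr(k, "expected digits after '/'")
          } else { i <- k; break }
        }
        toks[[length(toks) + 1L]] <- list(type = "spacer", lengths = lens)
      } else {
        toks[[length(toks) + 1L]] <- list(type = "spacer", lengths = 1L)
        i <- j
      }
    } else if (ch == "(") {
      j <- i + 1L
      res <- character(0)
      expect_res <- TRUE
      repeat {
        if (j > n) perr(i, "unterminated '('")
        if (expect_res) {
          if (!chars[j] %in% c(.AA20, "X")) perr(j, "expected residue letter")
          res <- c(res, chars[j])
          expect_res <- FALSE
        } else if (chars[j] == "/") {
          expect_res <- TRUE
        } else if (chars[j] == ")") {
          break
        } else perr(j, "expected '/' or ')'")
        j <- j + 1L
      }
      if (!length(res)) perr(i, "empty alternation")
      toks[[length(toks) + 1L]] <- list(type = "class", residues = res)
      i <- j + 1L
    } else if (ch %in% .AA20) {
      toks[[length(toks) + 1L]] <- list(type = "lit", residue = ch)
      i <- i + 1L
    } else {
      perr(i, paste0("unexpected character '", ch, "'"))
    }
  }
  toks
}

# Expand a token list into concrete regular expressions, one per choice of
# finite spacer alternatives. "Xn" stays as greedy ".*".
.signatureRegexes <- function(toks) {
  pieces <- lapply(toks, function(t) {
    switch(t$type,
      lit = t$residue,
      class = paste0("[", paste(t$residues, collapse = ""), "]"),
      any = ".*",
      spacer = vapply(t$lengths, function(k)
        if (k == 0L) "" else sprintf(".{%d}", k), character(1)))
  })
  combos <- expand.grid(pieces, stringsAsFactors = FALSE)
  apply(combos, 1L, paste, collapse = "")
}

#' Match a domain signature against a sequence
#'
#' Reports whether any substring of \code{seq} satisfies the signature and
#' the leftmost-longest matching span.
#'
#' @param seq Amino-acid string.
#' @param sig Signature pattern string (or a parsed token list from
#'   \code{\link{parseSignature}}).
#' @return List with \code{match} (logical) and, when matched,
#'   \code{start}/\code{end} (0-based half-open span), else \code{NA}s.
#' @examples
#' matchSignature("GAARYSAPAC", "GX2RYSX(P/R/A)XC")$match  # TRUE
#' matchSignature("LAYP", "LXYP")$match                    # TRUE
#' @export
matchSignature <- function(seq, sig) {
  toks <- if (is.character(sig)) parseSignature(sig) else sig
  regexes <- .signatureRegexes(toks)
  best_start <- NA_integer_
  best_len <- -1L
  for (r in regexes) {
    m <- regexpr(r, seq, perl = TRUE)
    if (m > 0L) {
      st <- as.integer(m)
      len <- attr(m, "match.length")
      if (is.na(best_start) || st < best_start ||
          (st == best_start && len > best_len)) {
        if (is.na(best_start) || st < best_start) { best_start <- st; best_len <- len }
        else best_len <- len
      }
    }
  }
  if (is.na(best_start))
    return(list(match = FALSE, start = NA_integer_, end = NA_integer_))
  list(match = TRUE, start = best_start - 1L, end = best_start - 1L + best_len)
}

#' Built-in domain signatures
#'
#' The cysteine-spacing signatures and short motifs used to annotate the
#' non-ICK superfamilies: the WAP four-disulfide core, the single-domain
#' von Willebrand factor type C (SVWC) domain, the astakine cytokine
#' pattern with its two short motifs, and the two knottin sub-group
#' patterns 4a/4b.
#'
#' @return Named character vector of signature patterns.
#' @examples
#' names(builtinSignatures())
#' @export
builtinSignatures <- function() {
  c(
    WAP       = "X_n_CPX_6/8_CX_6_CX_5_CX_5_CCX_3/4_CX_3_CX_n_",
    SVWC      = "X_13_CX_18/19_CX_4_CX_9_CX_8/11/12_CX_11_CCX_4_C",
    astakine  = "X_n_CX_5/6_CX_4_CCX_11_CX_9_CX_15/28/30_CX_1_CX_5_CX_4/6_CX_n_",
    GX2RYS    = "GX2RYSX(P/R/A)XC",
    LXYP      = "LXYP",
    group4a   = "X_20_CX_6_CX_5_CCX_11_CX_14_CX_2_CX_6_CX_2_",
    group4b   = "X_1_CX_6_CX_6_CCX_4_CX_1_CX_6_CX_1_CX_n_"
  )
}
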