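writeFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("FASTA reading preserves order, folds case and converts U to T", {
  f <- writeFasta(c(">c7142", "ATGAAA", ">c2 second record", "atguuu", "acg"))
  tx <- readTranscriptFasta(f)
  expect_equal(names(tx), c("c7142", "c2"))
  expect_equal(as.character(tx[[1]]), "ATGAAA")
  expect_equal(as.character(tx[[2]]), "ATGTTTACG")
  expect_true(all(is.na(S4Vectors::mcols(tx)$abundance)))
})

test_that("FASTA reading rejects illegal characters and warns on empty files", {
  f <- writeFasta(c(">bad", "ATJ"))
  expect_error(readTranscriptFasta(f), "bad")
  f2 <- writeFasta(character(0))
  expect_warning(tx <- readTranscriptFasta(f2), "empty")
  expect_length(tx, 0)
})

test_that("six-frame translation follows the frame conventions", {
  fr <- sixFrameTranslate("ATGAAA")
  expect_equal(fr[["+1"]], "MK")
  expect_equal(sixFrameTranslate("TTTCAT")[["-1"]], "MK")
  expect_error(sixFrameTranslate("AT"), "shorter")
  # trailing partial codons dropped; N codons become X
  fr2 <- sixFrameTranslate("ATGAANA")
  expect_equal(fr2[["+1"]], "MX")
  expect_equal(nchar(fr2[["+2"]]), 2)
})

test_that("ORF extraction keeps maximal M..stop segments above the length cut", {
  o1 <- extractOrfs(c("+1" = "MKKK*"), min_len = 3)
  expect_equal(o1$protein, "MKKK")
  expect_equal(c(o1$aa_start, o1$aa_end), c(0L, 4L))
  o2 <- extractOrfs(c("+1" = "AMK*MKKKK*"), min_len = 4)
  expect_equal(o2$protein, "MKKKK")
  expect_false(o2$incomplete)
  o3 <- extractOrfs(c("+1" = "AKKKKKK*"), min_len = 1)
  expect_equal(nrow(o3), 0)
  # incomplete ORF at frame end is flagged
  o4 <- extractOrfs(c("+1" = "AMKKK"), min_len = 3)
  expect_true(o4$incomplete)
})

test_that("reverse-complementing swaps frame signs but keeps the ORF multiset", {
  set.seed(11)
  for (rep in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 90 + rep, replace = TRUE),
                collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    a <- extractOrfs(sixFrameTranslate(nt), min_len = 5)
    b <- extractOrfs(sixFrameTranslate(rc), min_len = 5)
    expect_equal(sort(a$protein), sort(b$protein))
    sign_flip <- chartr("+-", "-+", a$frame)
    expect_setequal(paste(sign_flip, a$protein), paste(b$frame, b$protein))
  }
})

test_that("reported ORFs re-translate from their nucleotide interval", {
  set.seed(23)
  for (rep in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    tx <- Biostrings::DNAStringSet(nt)
    names(tx) <- "t1"
    orfs <- transcriptOrfs(tx, min_len = 4)
    for (i in seq_len(nrow(orfs))) {
      sub <- substr(nt, orfs$nt_start[i] + 1, orfs$nt_end[i])
      if (startsWith(orfs$frame[i], "-"))
        sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                 if.fuzzy.codon = "X"))
      expect_equal(sub("\\*$", "", prot), orfs$protein[i])
    }
  }
})
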