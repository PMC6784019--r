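test_that("contained fragments align at 100% identity over their full span", {
  al <- localAlign("IFECVFSCDIEK", "IFECVFSCDIEKEGKPCKPK")
  expect_equal(al$identity, 100)
  expect_equal(al$target_span, c(0L, 12L))
  expect_equal(al$query_span, c(0L, 12L))
})

test_that("X matches any residue and is excluded from the identity denominator", {
  al <- localAlign("CVFSCDXEK", "CVFSCDIEK")
  expect_equal(al$identity, 100)
  expect_equal(al$target_span, c(0L, 9L))
})

test_that("I/L are treated as identical under the default scheme", {
  expect_equal(localAlign("KIKK", "KLKK")$identity, 100)
  strict <- scoringScheme(il_equivalent = FALSE)
  expect_lt(localAlign("KIKK", "KLKK", strict)$identity, 100)
})

test_that("self-alignment scores the diagonal sum at full identity", {
  s <- scoringScheme()
  pep <- "IFECVFSCDIEK"
  al <- localAlign(pep, pep)
  aa <- strsplit(pep, "")[[1]]
  expect_equal(al$score, sum(diag(s$matrix[aa, aa])))
  expect_equal(al$identity, 100)
})

test_that("score and identity are invariant under query/target swap", {
  set.seed(41)
  for (rep in 1:10) {
    a <- randomPeptide(sample(5:15, 1))
    b <- randomPeptide(sample(5:15, 1))
    x <- localAlign(a, b)
    y <- localAlign(b, a)
    expect_equal(x$score, y$score)
    expect_equal(x$identity, y$identity)
  }
})

test_that("Smith-Waterman scores equal an independent Gotoh oracle", {
  set.seed(43)
  s <- scoringScheme()
  alpha <- c("A", "C", "D", "K")
  for (rep in 1:60) {
    a <- randomPeptide(sample(1:8, 1), alpha)
    b <- randomPeptide(sample(1:8, 1), alpha)
    got <- oracleLocalScore(a, b, s$matrix, open = -s$gap_open,
                            ext = -s$gap_extend)
    if (got == 0) next  # no positive-scoring pair: nothing to align
    expect_equal(localAlign(a, b, s)$score, got, info = paste(a, b))
  }
})

test_that("fragment search ranks targets and labels precursor regions", {
  prec <- segmentPrecursors(c(
    p1 = "MKTLVLVAVLGLALAEDAESEEARIFECVFSCDIEKEGKPCKPKGDDDDDDDDD"))
  frags <- data.frame(
    id = c("f_mature", "f_prop", "f_none"),
    sequence = c("IFECVFSCDIEK", "ALAEDAESEEAR", "WWWWW"),
    stringsAsFactors = FALSE)
  hits <- searchFragments(frags, prec, min_score = 15)
  expect_true(all(hits$fragment_id %in% c("f_mature", "f_prop")))
  expect_equal(hits$region[hits$fragment_id == "f_mature"], "mature")
  expect_equal(hits$region[hits$fragment_id == "f_prop"], "spanning")
  expect_false("f_none" %in% hits$fragment_id)
  # identical targets: identical scores, both reported, db order first
  db <- c(t1 = "IFECVFSCDIEK", t2 = "IFECVFSCDIEK")
  h2 <- searchFragments(c(q = "IFECVFSCDIEK"), db, min_score = 10)
  expect_equal(h2$target_id, c("t1", "t2"))
  expect_equal(h2$score[1], h2$score[2])
})

test_that("coverage is the union of spans, clipped, exact, and monotone", {
  expect_equal(computeCoverage(list(c(0, 21)), 32), 100 * 21 / 32)
  expect_equal(round(computeCoverage(list(c(0, 21)), 32)), 66)
  expect_equal(computeCoverage(list(c(0, 5), c(5, 10)), 10), 100)
  expect_equal(computeCoverage(list(), 10), 0)
  # overlap is not double counted; spans clip to the mature interval
  expect_equal(computeCoverage(list(c(0, 6), c(4, 10), c(-5, 2)), 10), 100)
  set.seed(47)
  for (rep in 1:10) {
    L <- sample(20:60, 1)
    spans <- lapply(1:6, function(i) {
      s <- sample(0:(L - 1), 1); c(s, min(L, s + sample(1:10, 1)))
    })
    cov <- vapply(1:6, function(k) computeCoverage(spans[1:k], L), numeric(1))
    expect_true(all(diff(cov) >= 0))
    expect_true(all(cov <= 100))
  }
  expect_error(computeCoverage(list(), 0), "mature_len")
})

test_that("the four catalogued fragments all top-rank the same precursor", {
  frags <- read.delim(system.file("extdata", "msms_fragments.tsv",
                                  package = "knotminer"))
  expect_equal(nrow(frags), 4)
  db <- S4Vectors::DataFrame(
    orf_id = c("c7142-like", "decoy"),
    signal = c("MKTLVLVAVLGLALA", ""),
    propeptide = c("EDIKLCLKIESEEAR", ""),
    mature = c("IFECVFSCDIEKEGKPCKPKGWWHHYYNNDD",
               "MGGGGHHHHDDDDEEEEGGGGHHHHDDDD"))
  hits <- searchFragments(frags, db, min_score = 15)
  top <- hits[!duplicated(hits$fragment_id), ]
  expect_setequal(top$fragment_id, frags$id)
  expect_true(all(top$target_id == "c7142-like"))
  # region labels from the segmentation: propeptide vs mature evidence
  expect_equal(top$region[top$fragment_id == "21-22/a-b_1"], "propeptide")
  expect_equal(top$region[top$fragment_id == "21-22/a-b_2"], "mature")
  # combined mature coverage of the three mature-region fragments
  mat_hits <- hits[hits$target_id == "c7142-like" & hits$region == "mature", ]
  off <- nchar(db$signal[1]) + nchar(db$propeptide[1])
  spans <- lapply(seq_len(nrow(mat_hits)), function(k)
    c(mat_hits$target_start[k] - off, mat_hits$target_end[k] - off))
  cov <- computeCoverage(spans, nchar(db$mature[1]))
  expect_gt(cov, 50)
  expect_lte(cov, 100)
})
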