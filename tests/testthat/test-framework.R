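test_that("framework extraction records order and adjacency of cysteines", {
  fw <- extractFramework("ADDCDDCDDCCDDC")
  expect_equal(canonicalPattern(fw), "C-C-CC-C")
  expect_equal(nCysteines(fw), 5L)
  expect_equal(cysteinePositions(fw), c(3L, 6L, 9L, 10L, 13L))
  expect_equal(canonicalPattern(extractFramework("AAAA")), "")
  expect_equal(canonicalPattern(extractFramework("CC")), "CC")
  expect_equal(canonicalPattern(extractFramework("ACCCA")), "CCC")
})

test_that("canonical pattern and positions are mutually consistent", {
  set.seed(5)
  for (rep in 1:20) {
    seq <- randomPeptide(sample(10:60, 1))
    fw <- extractFramework(seq)
    # rebuild adjacency from positions: gap 0 -> doublet, gap >= 1 -> '-'
    pos <- cysteinePositions(fw)
    rebuilt <- if (!length(pos)) "" else
      paste0("C", paste(ifelse(diff(pos) == 1, "C", "-C"), collapse = ""))
    if (length(pos) == 1) rebuilt <- "C"
    expect_equal(canonicalPattern(fw), rebuilt)
  }
})

test_that("superfamily classification matches the shipped scheme exactly", {
  defs <- superfamilyDefinitions()
  expect_equal(nrow(defs), 8)
  # the 10-cysteine pattern row parses to 10 cysteines
  sf8 <- defs[defs$superfamily == "SF8", ]
  expect_equal(nchar(gsub("-", "", sf8$canonical)), 10)
  expect_equal(classifySuperfamily("C-C-CC-C-C-C-C-C-C")$superfamily, "SF8")
  expect_equal(classifySuperfamily("C-C-C-CC-C")$superfamily, "SF2")
  expect_equal(classifySuperfamily("CCCC")$superfamily, "novel")
  # length range violations warn, never reject
  cl <- classifySuperfamily("C-C-CC-C", mature_len = 500)
  expect_equal(cl$superfamily, "SF1")
  expect_true(cl$length_warning)
  dup <- rbind(defs, defs[1, ])
  expect_error(classifySuperfamily("C-C-CC-C", dup), "duplicate")
})

test_that("framework clustering partitions by canonical pattern, order-invariantly", {
  pats <- c("C-C", "CC", "C-C", "C-CC", "CC")
  cl <- clusterFrameworks(pats)
  expect_equal(length(cl), 3)
  expect_equal(cl[["C-C"]], c(1L, 3L))
  # permutation leaves the partition (as sets of patterns) unchanged
  perm <- c(5, 3, 1, 2, 4)
  cl2 <- clusterFrameworks(pats[perm])
  expect_setequal(names(cl), names(cl2))
  for (p in names(cl)) expect_setequal(perm[cl2[[p]]], cl[[p]])
  expect_equal(length(clusterFrameworks(rep("C-C", 7))), 1)
  expect_equal(length(clusterFrameworks(character(0))), 0)
})

test_that("connectivity validation accepts disjoint in-range pairings", {
  v <- validateConnectivity(6, list(c(1, 4), c(2, 5), c(3, 6)))
  expect_true(v$valid)
  expect_length(v$free, 0)
  # five cysteines, bridges II-III and IV-V leave cysteine I free
  v2 <- validateConnectivity(5, list(c(2, 3), c(4, 5)))
  expect_true(v2$valid)
  expect_equal(v2$free, 1L)
  v3 <- validateConnectivity(4, list(c(1, 2), c(2, 3)))
  expect_false(v3$valid)
  expect_match(v3$reason, "reused")
  expect_false(validateConnectivity(4, list(c(1, 5)))$valid)
  expect_false(validateConnectivity(4, list(c(2, 2)))$valid)
})

test_that("shipped connectivity annotations validate against their frameworks", {
  defs <- superfamilyDefinitions()
  for (i in seq_len(nrow(defs))) {
    if (!nzchar(defs$connectivity[i])) next
    bonds <- lapply(strsplit(defs$connectivity[i], ";")[[1]],
                    function(b) as.integer(strsplit(b, "-")[[1]]))
    v <- validateConnectivity(defs$n_cys[i], bonds)
    expect_true(v$valid, info = defs$superfamily[i])
    free <- if (nzchar(defs$free_cys[i]))
      as.integer(strsplit(defs$free_cys[i], ";")[[1]]) else integer(0)
    expect_equal(v$free, free, info = defs$superfamily[i])
  }
})

test_that("logo matrices have unit column sums and closed-form information", {
  m <- consensusLogoMatrix(c("CAT", "CAT", "CAT"))
  expect_equal(unname(colSums(m$frequencies)), rep(1, 3))
  expect_equal(m$information[1], log2(20))
  # ten uniformly distinct residues: information log2(20) - log2(10)
  col10 <- vapply(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                  function(a) a, character(1))
  m10 <- consensusLogoMatrix(col10)
  expect_equal(m10$information[1], log2(20) - log2(10))
  # gaps are excluded from frequencies
  mg <- consensusLogoMatrix(c("A-", "A-", "AC"))
  expect_equal(unname(mg$frequencies["C", 2]), 1)
  expect_error(consensusLogoMatrix(c("AB", "A")), "ragged")
  expect_error(consensusLogoMatrix(character(0)), "empty")
})
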