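test_that("generated genes realize their superfamily pattern within range", {
  defs <- superfamilyDefinitions()
  set.seed(61)
  sf1 <- as.list(defs[defs$superfamily == "SF1", ])
  g <- generatePrecursorGene(sf1, generatorConfig())
  fw <- extractFramework(g$mature)
  expect_equal(canonicalPattern(fw), "C-C-CC-C")
  expect_equal(nCysteines(fw), 5L)
  expect_equal(nchar(g$mature), 54L)  # SF1 range is a single length
  expect_identical(paste0(g$signal, g$propeptide, g$mature), g$protein)
  # impossible length range errors out
  tiny <- list(superfamily = "bad", canonical = "C-C-C-C-C-C-C-C",
               len_min = 3, len_max = 5)
  expect_error(generatePrecursorGene(tiny, generatorConfig()), "range")
})

test_that("the generator is deterministic under a fixed seed", {
  b1 <- generateTranscriptome(generatorConfig(n_toxin_genes = 6, seed = 99))
  b2 <- generateTranscriptome(generatorConfig(n_toxin_genes = 6, seed = 99))
  expect_identical(as.character(b1$transcripts), as.character(b2$transcripts))
  expect_identical(as.data.frame(b1$truth), as.data.frame(b2$truth))
  cfg <- generatorConfig(n_toxin_genes = 6, seed = 99)
  expect_identical(simulateMaldi(b1$truth, cfg)$observed,
                   simulateMaldi(b2$truth, cfg)$observed)
  expect_identical(simulateTrypticFragments(b1$truth, cfg),
                   simulateTrypticFragments(b2$truth, cfg))
})

test_that("transcriptome TPMs are a proper per-million normalization", {
  cfg <- generatorConfig(n_toxin_genes = 8, seed = 12)
  b <- generateTranscriptome(cfg)
  tpm <- S4Vectors::mcols(b$transcripts)$abundance
  expect_equal(sum(tpm), 1e6, tolerance = 1e-3)
  expect_true(all(tpm > 0))
  # decoys are appended after the toxin genes
  expect_equal(length(b$transcripts), 8 + ceiling(0.1 * 8))
  # uniform mix over the scheme yields all 8 canonical patterns
  u <- generateTranscriptome(generatorConfig(
    n_toxin_genes = 8, seed = 3,
    superfamily_mix = setNames(rep(1 / 8, 8), paste0("SF", 1:8))))
  pats <- vapply(u$truth$mature,
                 function(m) canonicalPattern(extractFramework(m)),
                 character(1))
  expect_equal(length(unique(pats)), 8)
  # zero toxin genes: decoys only, empty truth
  z <- generateTranscriptome(generatorConfig(n_toxin_genes = 0, seed = 4))
  expect_equal(nrow(z$truth), 0)
})

test_that("noise-free MALDI simulation plants exact acid/amide mass pairs", {
  cfg <- generatorConfig(n_toxin_genes = 6, seed = 77, mass_noise_sd = 0,
                         amidation_fraction = 1)
  b <- generateTranscriptome(cfg)
  md <- simulateMaldi(b$truth, cfg)
  # masses equal the mass module's fully-oxidized values exactly
  for (i in seq_len(nrow(b$truth))) {
    m <- b$truth$mature[i]
    expect_true(any(abs(md$observed$neutral_mass -
      peptideMass(m, oxidizedModificationSet(m)$mods)) < 1e-9))
  }
  # every mature yields a pair differing by exactly the amide delta
  pairs <- detectAmidationPairs(md$observed, pair_tol = 1e-6)
  expect_gte(nrow(pairs), nrow(b$truth))
  expect_true(all(abs(pairs$delta - 0.98402) < 1e-6))
})

test_that("tryptic digestion respects K/R-not-before-P and missed cleavages", {
  d <- digestTryptic("AAKPDDKFF", missed = 0)
  expect_equal(d$sequence, c("AAKPDDK", "FF"))  # no cut at K before P
  d2 <- digestTryptic("IFECVFSCDIEKEGKPCKPKG", missed = 2)
  expect_true("IFECVFSCDIEK" %in% d2$sequence)
  # zero missed cleavages: no internal cleavable K/R
  d0 <- digestTryptic(randomPeptide(60), missed = 0)
  for (s in d0$sequence) {
    internal <- substr(s, 1, nchar(s) - 1)
    kr <- gregexpr("[KR]", internal)[[1]]
    if (kr[1] > 0)
      for (p in kr) expect_equal(substr(s, p + 1, p + 1), "P")
  }
  # flanks reconstruct the parent sequence context
  expect_equal(d$flank_n, c("-", "K"))
  expect_equal(d$flank_c, c("F", "-"))
})

test_that("simulated fragments carry carbamidomethylated m/z and spans", {
  cfg <- generatorConfig(n_toxin_genes = 4, seed = 21)
  b <- generateTranscriptome(cfg)
  fr <- simulateTrypticFragments(b$truth, cfg)
  expect_true(all(nchar(fr$sequence) >= cfg$min_fragment_len))
  i <- which(grepl("C", fr$sequence))[1]
  nc <- lengths(regmatches(fr$sequence[i], gregexpr("C", fr$sequence[i])))
  expect_equal(fr$mz[i],
               mz(peptideMass(fr$sequence[i],
                              modificationSet(carbamidomethyl = nc)),
                  fr$z[i]))
  # spans index into the planted mature peptide
  mat <- b$truth$mature[match(fr$transcript_id[i], b$truth$transcript_id)]
  expect_equal(substr(mat, fr$start[i] + 1, fr$end[i]), fr$sequence[i])
})
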