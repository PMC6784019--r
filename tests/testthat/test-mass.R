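test_that("residue masses agree with the elemental-composition oracle", {
  expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptideMass("G"), oracleMass("G"), tolerance = 1e-5)
  # de novo fragment observed in the CaV-active venom fraction
  pep <- "IFECVFSCDIEKEGKPCKPK"
  expect_equal(peptideMass(pep), oracleMass(pep), tolerance = 1e-4)
  set.seed(29)
  for (rep in 1:50) {
    s <- randomPeptide(sample(1:50, 1))
    expect_equal(peptideMass(s), oracleMass(s), tolerance = 1e-4)
  }
})

test_that("modification deltas are exact and validated", {
  s <- "IFECVFSCDIEK"
  base <- peptideMass(s)
  expect_equal(peptideMass(s, modificationSet(c_terminal_amide = TRUE)) - base,
               -0.98402)
  expect_equal(peptideMass(s, modificationSet(carbamidomethyl = 2)) - base,
               2 * 57.02146)
  expect_equal(peptideMass(s, modificationSet(disulfides = 1)) - base,
               -2 * 1.0078250319)
  expect_equal(peptideMass("MMM", modificationSet(met_oxidation = 3)) -
                 peptideMass("MMM"), 3 * 15.99491, tolerance = 1e-9)
  expect_error(peptideMass(s, modificationSet(disulfides = 2)), "disulfides")
  expect_error(peptideMass(s, modificationSet(disulfides = 1,
                                              carbamidomethyl = 1)), "exceed")
  expect_error(peptideMass("AXA"), "illegal")
  expect_error(peptideMass("MMM", modificationSet(met_oxidation = 4)),
               "methionines")
})

test_that("oxidized modification sets floor the bond count and flag odd cysteines", {
  even <- oxidizedModificationSet("CCCC")
  expect_equal(even$mods@disulfides, 2L)
  expect_equal(even$free_cys, 0L)
  odd <- oxidizedModificationSet("ACCCA")
  expect_equal(odd$mods@disulfides, 1L)
  expect_equal(odd$free_cys, 1L)
})

test_that("mass additivity holds without modifications", {
  set.seed(31)
  w <- massConstants()[["water"]]
  for (rep in 1:20) {
    a <- randomPeptide(sample(1:20, 1))
    b <- randomPeptide(sample(1:20, 1))
    expect_equal(peptideMass(paste0(a, b)),
                 peptideMass(a) + peptideMass(b) - w, tolerance = 1e-9)
  }
})

test_that("m/z follows the protonation formula", {
  expect_equal(mz(100, 1), 101.007276)
  expect_equal(mz(1545.683, 2), 773.849, tolerance = 1e-3)
  expect_error(mz(0, 1), "> 0")
  expect_error(mz(100, 0), "positive")
})

test_that("mass matching reports all combinations within tolerance, best first", {
  pep <- "IFECVFSCDIEKEGKPCKPKG"
  amide <- peptideMass(pep, oxidizedModificationSet(pep, TRUE)$mods)
  obs <- data.frame(fraction_id = c("F1", "F2"),
                    neutral_mass = c(amide, amide + 10))
  m <- matchMasses(pep, obs, tol = 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$delta, 0)
  expect_equal(m$mod_label, "oxidized_amide")
  none <- matchMasses(pep, data.frame(fraction_id = "F1", neutral_mass = 999),
                      tol = 0.5)
  expect_equal(nrow(none), 0)
  expect_error(matchMasses(pep, obs, tol = 0), "tol")
})

test_that("amidation pair detection matches the venom-fraction observation", {
  # the 3810.6 Da acid form and 3809.61 Da amide form differ by ~1 Da
  p <- detectAmidationPairs(c(3810.60, 3809.61), pair_tol = 0.05)
  expect_equal(nrow(p), 1)
  expect_equal(p$delta, 0.99)
  expect_equal(p$rounded_delta, 1)
  expect_equal(nrow(detectAmidationPairs(c(100, 200))), 0)
  exact <- detectAmidationPairs(c(500, 500 + 0.98402))
  expect_equal(exact$delta, 0.98402)
  # symmetric and order-independent
  a <- detectAmidationPairs(c(3809.61, 3810.60, 2000))
  expect_equal(as.data.frame(a), as.data.frame(p))
})
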