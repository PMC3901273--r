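test_that("single-element patterns follow multinomial isotopologue statistics", {
  c1 <- elementPattern("C", 1)
  expect_equal(c1$abundance, c(0.98890, 0.01110))
  expect_equal(c1$mass, c(12.0, 13.003354838), tolerance = 1e-9)

  c2 <- elementPattern("C", 2)
  expect_equal(length(c2$mass), 3)
  expect_equal(c2$abundance,
               c(0.98890^2, 2 * 0.98890 * 0.01110, 0.01110^2),
               tolerance = 1e-12)

  c0 <- elementPattern("C", 0)
  expect_equal(c0$mass, 0)
  expect_equal(c0$abundance, 1)

  expect_error(elementPattern("C", -1), "non-negative")
  expect_error(elementPattern("Xx", 2), "unknown element")
})

test_that("isotopologue counts equal the multiset coefficient", {
  tab <- isotopeTable()
  byR <- list(`1` = "P", `2` = "C", `3` = "O")
  for (r in 1:3) {
    el <- byR[[as.character(r)]]
    expect_equal(length(tab[[el]]$mass), r)
    for (l in c(1, 2, 5, 10, 20)) {
      p <- elementPattern(el, l)
      expect_equal(length(p$mass), choose(l + r - 1, r - 1))
      expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    }
  }
})

test_that("formula parsing reads Hill notation and rejects junk", {
  expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L),
               ignore_attr = TRUE)
  expect_equal(unname(parseFormula("CHCl3")), c(1L, 1L, 3L))
  expect_error(parseFormula("C6H12-O6"), "cannot parse")
  expect_error(moleculePattern("C2Qq3"), "unknown element")
})

test_that("molecule patterns convolve elements and stay normalized", {
  g <- moleculePattern("C6H12O6", pruneBelow = 0, mergeTol = 1e-9)
  expect_equal(sum(g$abundance), 1, tolerance = 1e-9)
  expect_equal(g$mass[1], 180.0634, tolerance = 1e-3)
  expect_false(is.unsorted(g$mass))

  ## single-element reduction
  p1 <- moleculePattern("C2", pruneBelow = 0, mergeTol = 0)
  p2 <- elementPattern("C", 2)
  expect_equal(p1$mass, p2$mass, tolerance = 1e-12)
  expect_equal(p1$abundance, p2$abundance, tolerance = 1e-12)

  ## element order in the formula string does not matter
  a <- moleculePattern("C3N2", pruneBelow = 0, mergeTol = 1e-9)
  b <- moleculePattern("N2C3", pruneBelow = 0, mergeTol = 1e-9)
  expect_equal(a$mass, b$mass, tolerance = 1e-10)
  expect_equal(a$abundance, b$abundance, tolerance = 1e-12)
})

test_that("small-formula patterns equal exhaustive isotopologue enumeration", {
  for (f in c("C3N2", "C2H3", "OS")) {
    got <- moleculePattern(f, pruneBelow = 0, mergeTol = 1e-5)
    brute <- bruteMoleculePattern(f)
    expect_equal(length(got$mass), nrow(brute))
    expect_equal(got$mass, brute$mass, tolerance = 1e-4)
    expect_equal(got$abundance, brute$ab, tolerance = 1e-10)
  }
})

test_that("pattern-to-spectrum conversion applies the adduct shift", {
  p <- moleculePattern("C6H12O6")
  pos <- patternToSpectrum(p, "positive")
  expect_equal(peakMasses(pos)[1], p$mass[1] + 1.007276466, tolerance = 1e-9)
  expect_equal(msLevel(pos), 1L)
  expect_equal(sum(peakIntensities(pos)), 1, tolerance = 1e-12)
  neg <- patternToSpectrum(p, "negative")
  expect_equal(peakMasses(neg)[1], p$mass[1] - 1.007276466, tolerance = 1e-9)
})

test_that("isotope matching scores the generating formula highest", {
  params <- KernelParams(sigmaMass = 0.01, sigmaIntensity = 0.05,
                         variants = "peaks")
  truth <- "C10H14N2O4"
  obs <- patternToSpectrum(moleculePattern(truth), "positive")
  self <- isotopeMatchScore(obs, moleculePattern(truth), "positive", params)
  expect_equal(self, 1, tolerance = 1e-9)

  ## a pattern shifted far away barely overlaps
  far <- moleculePattern("C30H40N2O4")
  expect_lt(isotopeMatchScore(obs, far, "positive", params), 1e-6)

  ## delegation: the score is the normalized peaks kernel of the two spectra
  decoy <- moleculePattern("C11H14N2O4")
  theo <- patternToSpectrum(decoy, "positive")
  expect_equal(isotopeMatchScore(obs, decoy, "positive", params),
               kernelValue(obs, theo, "peaks", params) /
                 sqrt(kernelValue(obs, obs, "peaks", params) *
                        kernelValue(theo, theo, "peaks", params)),
               tolerance = 1e-12)

  ## the generating formula beats one-carbon decoys
  decoys <- c("C9H14N2O4", "C11H14N2O4", "C10H14N2O5")
  scores <- vapply(decoys, function(f)
    isotopeMatchScore(obs, moleculePattern(f), "positive", params), numeric(1))
  expect_true(all(scores < self))

  expect_error(isotopeMatchScore(MassSpectrum(numeric(0), numeric(0),
                                              msLevel = 1L),
                                 moleculePattern(truth), "positive"), "empty")
})

test_that("rank aggregation fuses two orderings under all three schemes", {
  fp <- data.frame(rank = 1:4, moleculeId = c("A", "B", "C", "D"),
                   logScore = c(-1, -2, -3, -4))
  isoSame <- data.frame(rank = 1:4, moleculeId = c("A", "B", "C", "D"),
                        logScore = c(0.9, 0.8, 0.7, 0.6))
  for (m in c("average", "minrank", "rerank")) {
    agg <- aggregateRanks(fp, isoSame, m)
    expect_identical(agg$moleculeId, c("A", "B", "C", "D"))
    expect_identical(agg$rank, 1:4)
  }

  ## average-rank tie (ranks (2,4) vs (3,3) both average 3) broken by id
  fp2 <- data.frame(rank = c(1, 2, 3), moleculeId = c("X", "B", "A"),
                    logScore = c(-1, -2, -3))
  iso2 <- data.frame(rank = c(1, 4, 3), moleculeId = c("X", "B", "A"),
                     logScore = c(1, 0.2, 0.3))
  ## B: ranks (2,4) -> 3; A: ranks (3,3) -> 3; tie broken by id: A first
  agg2 <- aggregateRanks(fp2, iso2[c(1, 2, 3), ], "average")
  expect_identical(agg2$moleculeId, c("X", "A", "B"))

  ## rerank with all isotope scores equal reduces to the fingerprint order
  isoFlat <- data.frame(rank = 1:4, moleculeId = c("D", "C", "B", "A"),
                        logScore = rep(0.5, 4))
  agg3 <- aggregateRanks(fp, isoFlat, "rerank")
  expect_identical(agg3$moleculeId, fp$moleculeId)

  expect_error(aggregateRanks(fp, isoSame[1:3, ], "average"), "same candidate")
})
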