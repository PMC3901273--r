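test_that("peak-pair integral has the analytic self-value and Gaussian decay", {
  p <- KernelParams(sigmaMass = 0.01, sigmaIntensity = 0.1)
  expect_equal(peakPairIntegral(100, 0.5, 100, 0.5, p),
               1 / (4 * pi * 0.01 * 0.1), tolerance = 1e-14)
  expect_equal(peakPairIntegral(100, 0.2, 101, 0.8, p),
               peakPairIntegral(101, 0.8, 100, 0.2, p))
  vals <- peakPairIntegral(100, 0.5, 100 + c(0.005, 0.01, 0.02, 0.05), 0.5, p)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
  expect_error(KernelParams(sigmaMass = 0), "positive")
})

test_that("closed-form integral matches independent 2-D quadrature", {
  p <- KernelParams(sigmaMass = 0.01, sigmaIntensity = 0.1)
  got <- peakPairIntegral(100.0, 0.5, 100.02, 0.5, p)
  want <- quadPeakIntegral(100.0, 0.5, 100.02, 0.5, 0.01, 0.1)
  expect_equal(got, want, tolerance = 1e-8)

  set.seed(21)
  for (i in 1:25) {
    sm <- runif(1, 0.005, 0.5); si <- runif(1, 0.01, 0.3)
    m1 <- runif(1, 50, 500); i1 <- runif(1, 0, 1)
    m2 <- m1 + rnorm(1, 0, 2 * sm); i2 <- i1 + rnorm(1, 0, 2 * si)
    got <- peakPairIntegral(m1, i1, m2, abs(i2),
                            KernelParams(sigmaMass = sm, sigmaIntensity = si))
    want <- quadPeakIntegral(m1, i1, m2, abs(i2), sm, si)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("mass-loss transform subtracts from the precursor and involutes", {
  s <- MassSpectrum(c(100.05, 181.07), c(0.3, 0.7), precursorMz = 181.07)
  l <- lossSpectrum(s)
  expect_equal(peakMasses(l)[2], 181.07 - 100.05, tolerance = 1e-9)
  expect_equal(peakIntensities(l)[2], 0.3)
  ## peak at the precursor mass survives as a (tiny) zero loss
  expect_lt(peakMasses(l)[1], 1e-12)
  ## applying the transform twice recovers the original masses
  back <- lossSpectrum(l)
  expect_equal(sort(peakMasses(back)), sort(peakMasses(s)), tolerance = 1e-9)

  noPrec <- MassSpectrum(100, 1)
  expect_error(lossSpectrum(noPrec), "precursor")
  above <- MassSpectrum(c(100, 190), c(1, 1), precursorMz = 181)
  expect_warning(l2 <- lossSpectrum(above), "dropped")
  expect_equal(nPeaks(l2), 1)
})

test_that("kernel values reduce to the pair integral and match brute force", {
  p <- KernelParams(sigmaMass = 0.02, sigmaIntensity = 0.08)
  s1 <- MassSpectrum(120.5, 1, precursorMz = 200)
  s2 <- MassSpectrum(120.52, 0.8, precursorMz = 200)
  expect_equal(kernelValue(s1, s2, "peaks", p),
               peakPairIntegral(120.5, 1, 120.52, 0.8, p), tolerance = 1e-14)

  set.seed(5)
  for (i in 1:5) {
    a <- randomSpectrum(5); b <- randomSpectrum(5)
    expect_equal(kernelValue(a, b, "peaks", p),
                 brutePeaksKernel(peakMatrix(a), peakMatrix(b), p),
                 tolerance = 1e-12)
    expect_equal(kernelValue(a, b, "mloss", p),
                 brutePeaksKernel(peakMatrix(lossSpectrum(a)),
                                  peakMatrix(lossSpectrum(b)), p),
                 tolerance = 1e-12)
    expect_equal(kernelValue(a, b, "diff", p),
                 brutePeaksKernel(bruteDiffPeaks(peakMatrix(a)),
                                  bruteDiffPeaks(peakMatrix(b)), p),
                 tolerance = 1e-12)
  }
  expect_error(kernelValue(MassSpectrum(numeric(0), numeric(0)), s1), "empty")
})

test_that("the difference representation grows quadratically in peak count", {
  s <- randomSpectrum(10)
  expect_equal(nrow(fingerMS:::.diffPeaks(peakMatrix(s))), choose(10, 2))
  s2 <- randomSpectrum(20)
  expect_equal(nrow(fingerMS:::.diffPeaks(peakMatrix(s2))), choose(20, 2))
  expect_error(kernelValue(MassSpectrum(100, 1), MassSpectrum(100, 1), "diff"),
               "two peaks")
})

test_that("kernels are symmetric and positive for all variants", {
  p <- KernelParams(variants = c("peaks", "mloss", "diff"))
  set.seed(9)
  for (i in 1:5) {
    a <- randomSpectrum(4); b <- randomSpectrum(6)
    for (v in c("peaks", "mloss", "diff")) {
      expect_equal(kernelValue(a, b, v, p), kernelValue(b, a, v, p),
                   tolerance = 1e-12)
      expect_gt(kernelValue(a, a, v, p), 0)
    }
  }
})

test_that("normalization and combination obey the Cauchy-Schwarz bound", {
  ## a broad mass sigma keeps the cross-kernel well above the underflow
  ## regime for randomly placed peaks
  p <- KernelParams(sigmaMass = 20, sigmaIntensity = 0.3,
                    variants = c("peaks", "mloss"))
  set.seed(33)
  a <- randomSpectrum(5); b <- randomSpectrum(5)
  vals <- sapply(c(peaks = "peaks", mloss = "mloss"),
                 function(v) kernelValue(a, b, v, p))
  sa <- sapply(c(peaks = "peaks", mloss = "mloss"),
               function(v) kernelValue(a, a, v, p))
  sb <- sapply(c(peaks = "peaks", mloss = "mloss"),
               function(v) kernelValue(b, b, v, p))
  comb <- normalizeAndCombine(vals, sa, sb, p)
  expect_gt(comb, 0)
  expect_lte(comb, 2)
  ## identical spectra: each normalized variant contributes exactly 1
  expect_equal(normalizeAndCombine(sa, sa, sa, p), 2, tolerance = 1e-12)
  ## single-variant pass-through
  p1 <- KernelParams(variants = "peaks")
  expect_equal(normalizeAndCombine(vals["peaks"], sa["peaks"], sb["peaks"], p1),
               vals[["peaks"]] / sqrt(sa[["peaks"]] * sb[["peaks"]]))
  expect_error(normalizeAndCombine(vals, c(peaks = 0, mloss = 1), sb, p),
               "self-similarity")
})

test_that("square Gram matrices are symmetric PSD with unit diagonal", {
  set.seed(31)
  specs <- replicate(10, randomSpectrum(6), simplify = FALSE)
  names(specs) <- sprintf("q%02d", 1:10)
  g <- gramMatrix(specs, params = KernelParams(variants = c("peaks", "mloss")))
  K <- gramValues(g)
  expect_equal(K, t(K), tolerance = 1e-10)
  expect_equal(unname(diag(K)), rep(1, 10), tolerance = 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-9 * sum(diag(K)) / nrow(K))
})

test_that("cross Grams agree with the corresponding pooled square block", {
  set.seed(17)
  a <- replicate(4, randomSpectrum(5), simplify = FALSE)
  b <- replicate(3, randomSpectrum(5), simplify = FALSE)
  names(a) <- paste0("a", 1:4); names(b) <- paste0("b", 1:3)
  p <- KernelParams(variants = c("peaks", "mloss"))
  cross <- gramValues(gramMatrix(a, b, params = p))
  pooled <- gramValues(gramMatrix(c(a, b), params = p))
  expect_equal(cross, pooled[1:4, 5:7], tolerance = 1e-12)
})

test_that("Gram matrices survive a text round trip", {
  set.seed(2)
  specs <- replicate(3, randomSpectrum(4), simplify = FALSE)
  g <- gramMatrix(specs)
  tf <- withr::local_tempfile()
  writeGramMatrix(g, tf)
  g2 <- readGramMatrix(tf)
  expect_equal(gramValues(g2), gramValues(g), tolerance = 1e-12)
  expect_equal(sigmaMass(kernelParams(g2)), sigmaMass(kernelParams(g)))
})

test_that("replicate variance estimation recovers known jitter and floors zeros", {
  base <- MassSpectrum(c(100, 150, 200), c(1, 2, 3), precursorMz = 250)
  identicalGroup <- list(base, base, base)
  est <- estimatePeakVariances(list(identicalGroup))
  expect_equal(unname(est["sigmaMass"]), 1e-4)
  expect_equal(unname(est["sigmaIntensity"]), 1e-3)

  set.seed(77)
  groups <- replicate(100, {
    masses <- c(100, 150, 200)
    lapply(1:2, function(i)
      MassSpectrum(masses + rnorm(3, 0, 0.01), c(1, 2, 3), precursorMz = 250))
  }, simplify = FALSE)
  est2 <- estimatePeakVariances(groups)
  expect_lt(abs(est2[["sigmaMass"]] - 0.01) / 0.01, 0.2)

  expect_error(estimatePeakVariances(list(list(base))), "default")
})
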