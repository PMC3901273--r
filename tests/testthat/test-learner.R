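test_that("grouped folds never split a molecule and balance spectrum counts", {
  molOf <- stats::setNames(rep(sprintf("mol%02d", 1:10), each = 3),
                           sprintf("s%02d", 1:30))
  fa <- makeGroupedFolds(molOf, 10, seed = 4)
  expect_equal(sort(unique(fa$fold)), 1:10)
  ## one molecule per fold when k equals the molecule count
  expect_equal(as.integer(table(fa$moleculeFold)), rep(1L, 10))
  perMol <- tapply(fa$fold, molOf, function(x) length(unique(x)))
  expect_true(all(perMol == 1))

  ## round-robin dealing balances molecule counts across folds to within 1
  set.seed(8)
  nspec <- sample(1:5, 100, replace = TRUE)
  molOf2 <- stats::setNames(rep(sprintf("m%03d", 1:100), times = nspec),
                            sprintf("t%04d", seq_len(sum(nspec))))
  fa2 <- makeGroupedFolds(molOf2, 10, seed = 1)
  molCounts <- table(fa2$moleculeFold)
  expect_lte(max(molCounts) - min(molCounts), 1)
  perMol2 <- tapply(fa2$fold, molOf2, function(x) length(unique(x)))
  expect_true(all(perMol2 == 1))

  expect_error(makeGroupedFolds(molOf[1:9], 10), "fewer molecules")
  expect_identical(makeGroupedFolds(molOf, 5, seed = 2),
                   makeGroupedFolds(molOf, 5, seed = 2))
})

test_that("bit SVMs separate a separable toy problem and agree with a QP solver", {
  toy <- linearToyGram(n = 24)
  m <- trainBitSVM(toy$K, toy$labels, C = 10, tol = 1e-9)
  expect_false(m$constant)
  dec <- toy$K[, m$support, drop = FALSE] %*% m$alphaY + m$bias
  expect_true(all(sign(dec) == toy$labels))

  ## independent oracle: generic quadratic-programming solution of the
  ## SVM dual (ipop), a different code path from the SMO optimizer
  y <- toy$labels; K <- toy$K; C <- 10; n <- length(y)
  H <- (y %*% t(y)) * K
  qp <- kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0, sigf = 12)
  alpha <- kernlab::primal(qp)
  ## bias from a margin support vector (0 < alpha < C)
  onMargin <- which(alpha > 1e-4 & alpha < C - 1e-4)
  fNoB <- K %*% (alpha * y)
  bQP <- mean(y[onMargin] - fNoB[onMargin])
  decQP <- fNoB + bQP
  expect_equal(as.numeric(dec), as.numeric(decQP), tolerance = 1e-6)

  const <- trainBitSVM(toy$K, rep(1, 24), C = 1)
  expect_true(const$constant)
  expect_equal(const$value, 1)
})

test_that("C selection maximizes grouped CV accuracy with small-C tie-break", {
  toy <- linearToyGram(n = 30)
  folds <- makeGroupedFolds(toy$moleculeOf, 5, seed = 1)
  expect_equal(selectC(toy$K, toy$labels, folds, grid = 7), 7)
  expect_equal(selectC(toy$K, toy$labels, folds, grid = 1), 1)

  ## a vanishingly small C underfits by construction (decision collapses
  ## to the zero rule), so the selected C must exceed the grid minimum
  sel <- selectC(toy$K, toy$labels, folds, grid = c(1e-8, 1))
  expect_gt(sel, 1e-8)

  ## grid order is irrelevant (sorted internally); accuracy ties go to the
  ## smaller C, so two perfect values select the smaller one
  expect_equal(selectC(toy$K, toy$labels, folds, grid = c(10, 1)),
               selectC(toy$K, toy$labels, folds, grid = c(1, 10)))
  ## zero decision values map to +1 (documented tie rule)
  expect_identical(fingerMS:::.signPlus(c(0, -0.1, 0.1)), c(1L, -1L, 1L))
  expect_error(selectC(toy$K, toy$labels, folds, grid = numeric(0)),
               "non-empty")
})

test_that("cross-validated reliability reflects held-out accuracy exactly", {
  toy <- linearToyGram(n = 24)
  folds <- makeGroupedFolds(toy$moleculeOf, 4, seed = 2)
  fpm <- cbind(separable = toy$labels)

  w <- crossValidatedReliability(toy$K, fpm, folds, toy$moleculeOf, grid = 10,
                                 innerK = 2)
  expect_equal(unname(w["separable"]), 1.0)

  ## labels identical to the fold indicator: every training complement is
  ## trained on the other folds and the k=2 case is fully constant-model
  fold2 <- makeGroupedFolds(toy$moleculeOf, 2, seed = 3)
  yFold <- ifelse(fold2$fold == 1, 1, -1)
  w2 <- crossValidatedReliability(toy$K, cbind(foldbit = unname(yFold)),
                                  fold2, toy$moleculeOf, grid = 1, innerK = 2)
  ## training data for fold 1 is all -1 (constant -1 predictor), tested on
  ## all +1 labels, and vice versa: accuracy is exactly zero
  expect_equal(unname(w2["foldbit"]), 0)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("prediction is deterministic and recovers training labels on a clean world", {
  w <- generateToyWorld(nMolecules = 16, mBits = 6, peaksPerMolecule = 2,
                        massJitterSd = 0, spectraPerMolecule = 2, seed = 11)
  fpS <- fingerprints(w$candidates)[w$moleculeOf, ]
  model <- trainFingerprintModel(w$spectra, fpS, moleculeOf = w$moleculeOf,
                                 k = 4, innerK = 2, grid = 10, seed = 5)
  query <- w$spectra[[1]]
  p1 <- predictFingerprints(model, query)
  p2 <- predictFingerprints(model, query)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% c(-1L, 1L)))
  ## zero mass jitter + strong planted signal: a training spectrum maps
  ## back to its own molecule's bits
  truth <- fingerprints(w$candidates)[w$moleculeOf[1], model@mask]
  expect_identical(as.integer(p1), as.integer(truth))
  expect_identical(attr(p1, "schemaHash"), model@schemaHash)
})

test_that("all-constant models predict without touching the kernel", {
  keys <- c("k1", "k2")
  model <- new("FingerprintModel", version = "1",
               kernelParams = KernelParams(), keyNames = keys,
               mask = c(TRUE, TRUE), reliability = c(0.9, 0.9),
               bitModels = list(
                 list(constant = TRUE, value = 1, alphaY = numeric(0),
                      support = integer(0), bias = 0, C = 1),
                 list(constant = TRUE, value = -1, alphaY = numeric(0),
                      support = integer(0), bias = 0, C = 1)),
               trainingSpectra = list(), trainingIds = character(0),
               moleculeOf = character(0),
               selfSim = matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("peaks", "mloss"))),
               schemaHash = fingerprintSchemaHash(keys), seed = 1L)
  ## an empty query would break any kernel evaluation; constants bypass it
  empty <- new("MassSpectrum")
  expect_identical(as.integer(predictFingerprints(model, empty)), c(1L, -1L))
})

test_that("model bundles round trip through the text format", {
  w <- generateToyWorld(nMolecules = 10, mBits = 5, spectraPerMolecule = 2,
                        seed = 3)
  fpS <- fingerprints(w$candidates)[w$moleculeOf, ]
  model <- trainFingerprintModel(w$spectra, fpS, moleculeOf = w$moleculeOf,
                                 k = 3, innerK = 2, grid = 1, seed = 2)
  dir <- withr::local_tempdir()
  writeFingerprintModel(model, dir)
  model2 <- readFingerprintModel(dir)
  expect_equal(model2@reliability, model@reliability, tolerance = 1e-12)
  expect_identical(model2@mask, model@mask)
  expect_identical(model2@schemaHash, model@schemaHash)
  q <- w$spectra[[5]]
  expect_identical(predictFingerprints(model2, q),
                   predictFingerprints(model, q))
})
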