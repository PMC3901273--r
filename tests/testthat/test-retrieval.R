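test_that("the ppm mass window keeps exactly the in-window records", {
  fp <- matrix(1L, 4, 2, dimnames = list(NULL, c("a", "b")))
  fp[, 2] <- -1L
  db <- CandidateSet(c("A", "B", "C", "D"),
                     c(180.042224, 180.0430, 180.0445, 250), fp)
  ## ppm = 0: only exact matches survive
  expect_identical(candidateIds(massWindowFilter(db, 180.042224, 0)), "A")
  ## 10 ppm window at this mass is 1.80e-3 Da wide on each side
  hits <- massWindowFilter(db, 180.042224, 10)
  expect_identical(candidateIds(hits), c("A", "B"))

  set.seed(41)
  masses <- runif(50, 100, 500)
  db2 <- CandidateSet(sprintf("R%02d", 1:50), masses,
                      matrix(1L, 50, 1, dimnames = list(NULL, "k")))
  q <- 300; ppm <- 5000
  brute <- sprintf("R%02d", which(abs(masses - q) / q * 1e6 <= ppm))
  expect_identical(candidateIds(massWindowFilter(db2, q, ppm)), brute)
  expect_equal(length(massWindowFilter(db2, 300, 0)), 0)
})

test_that("Poisson-binomial scores behave as a per-bit likelihood", {
  m <- 20
  y <- rep(1, m)
  expect_equal(poissonBinomialLogScore(y, y, rep(1 - 1e-6, m)),
               m * log(1 - 1e-6))
  ## uninformative bits: score independent of the fingerprint
  flip <- y; flip[1:7] <- -1
  expect_equal(poissonBinomialLogScore(y, y, rep(0.5, m)), m * log(0.5))
  expect_equal(poissonBinomialLogScore(flip, y, rep(0.5, m)), m * log(0.5))
  ## clipping keeps w = 0 and w = 1 finite
  expect_true(is.finite(poissonBinomialLogScore(y, flip, rep(1, m))))
  expect_error(poissonBinomialLogScore(y, y[-1], rep(0.9, m - 1)), "mismatch")
})

test_that("exp(score) over the full fingerprint space sums to one", {
  set.seed(19)
  m <- 10
  w <- runif(m, 0.05, 0.95)
  yhat <- sample(c(-1, 1), m, replace = TRUE)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  total <- sum(apply(grid, 1, function(y)
    exp(poissonBinomialLogScore(yhat, y, w))))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("flipping agreement moves the score in the direction of reliability", {
  m <- 12
  y <- rep(1, m)
  w <- rep(0.9, m)
  base <- poissonBinomialLogScore(y, y, w)
  off <- y; off[3] <- -1
  expect_lt(poissonBinomialLogScore(y, off, w), base)
  ## an unreliable bit (w < 0.5) rewards disagreement
  w2 <- w; w2[3] <- 0.2
  expect_gt(poissonBinomialLogScore(y, off, w2),
            poissonBinomialLogScore(y, y, w2))
})

test_that("candidate ranking is score-sorted with deterministic id tie-break", {
  set.seed(23)
  m <- 16
  yhat <- sample(c(-1L, 1L), m, replace = TRUE)
  fp <- rbind(yhat,
              replicate(4, {
                z <- yhat; flips <- sample(m, sample(2:5, 1)); z[flips] <- -z[flips]; z
              }) |> t())
  colnames(fp) <- sprintf("BIT_%03d", 1:m)
  db <- toyCandidates(fp)
  w <- rep(0.85, m)
  r <- rankCandidates(db, yhat, w, queryId = "q")
  expect_identical(r$moleculeId[1], "M01")  # exact match wins
  expect_identical(r$rank, 1:5)
  expect_true(all(diff(r$logScore) <= 0))
  expect_identical(attr(r, "queryId"), "q")

  ## identical fingerprints: equal scores, consecutive ranks by id
  twin <- toyCandidates(rbind(yhat, yhat), ids = c("Z9", "A1"))
  rt <- rankCandidates(twin, yhat, w)
  expect_equal(rt$logScore[1], rt$logScore[2])
  expect_identical(rt$moleculeId, c("A1", "Z9"))

  ## brute-force oracle over 50 random candidates
  fp50 <- matrix(sample(c(-1L, 1L), 50 * m, replace = TRUE), 50, m)
  colnames(fp50) <- colnames(fp)
  db50 <- toyCandidates(fp50)
  w50 <- runif(m, 0.2, 0.98)
  r50 <- rankCandidates(db50, yhat, w50)
  bruteScores <- vapply(seq_len(50), function(i)
    poissonBinomialLogScore(fp50[i, ], yhat, w50), numeric(1))
  bruteOrder <- candidateIds(db50)[order(-bruteScores, candidateIds(db50))]
  expect_identical(r50$moleculeId, bruteOrder)
  expect_equal(r50$logScore,
               bruteScores[match(r50$moleculeId, candidateIds(db50))],
               tolerance = 1e-12)

  empty <- rankCandidates(db50[integer(0)], yhat, w50)
  expect_equal(nrow(empty), 0)
})

test_that("uniqueness statistics count fingerprint duplicates correctly", {
  fpA <- c(1L, 1L, -1L); fpB <- c(1L, -1L, 1L)
  db <- toyCandidates(rbind(fpA, fpA, fpB), masses = c(200, 210, 220))
  st <- fingerprintUniquenessStats(db)
  expect_equal(st$table$nMolecules[st$table$N_dp == 2], 2)
  expect_equal(st$table$nMolecules[st$table$N_dp == 1], 1)
  expect_equal(st$uniqueFingerprintFraction, 1 / 3)
  ## the two duplicates differ in mass, so the (fingerprint, mass) pair is
  ## unique for everyone
  expect_equal(st$uniqueFingerprintMassFraction, 1)

  dbSame <- toyCandidates(rbind(fpA, fpA, fpB), masses = c(200, 200, 220))
  expect_equal(fingerprintUniquenessStats(dbSame)$uniqueFingerprintMassFraction,
               1 / 3)

  allDistinct <- toyCandidates(rbind(fpA, fpB))
  st2 <- fingerprintUniquenessStats(allDistinct)
  expect_equal(st2$uniqueFingerprintFraction, 1)
  expect_true(all(st2$table$N_dp == 1))
})
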