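#' @include learner.R retrieval.R synthetic.R
NULL

## Train one SVM per bit on K[tr, tr] and predict the rows in `te`.
.trainPredictBits <- function(K, fpS, tr, te, grid, folds = NULL) {
  pred <- matrix(NA_integer_, length(te), ncol(fpS))
  for (j in seq_len(ncol(fpS))) {
    y <- fpS[tr, j]
    C <- if (length(grid) > 1 && !is.null(folds)) {
      if (length(unique(y)) > 1) selectC(K[tr, tr, drop = FALSE], y, folds, grid)
      else grid[1]
    } else grid[1]
    m <- trainBitSVM(K[tr, tr, drop = FALSE], y, C)
    pred[, j] <- .signPlus(.bitDecision(m, K[te, tr, drop = FALSE]))
  }
  pred
}

#' Learning-curve experiment on a synthetic world
#'
#' Measures how fingerprint prediction and retrieval improve with training
#' set size. For each outer molecule-grouped fold, increasing fractions of
#' the remaining molecules are used as training data; held-out spectra are
#' predicted bit-wise and the true molecule is retrieved from the world's
#' candidate set. Reported per fraction: the mean held-out bit error and
#' the mean relative rank of the true molecule. Candidate ranking uses a
#' uniform reliability of 0.75 for every bit, so the rank metric isolates
#' the quality of the predicted fingerprints from reliability estimation.
#'
#' @param world a `ToyWorld` from [generateToyWorld()].
#' @param fractions training fractions of the per-fold molecule pool.
#' @param k outer fold count.
#' @param grid SVM cost grid (a single value skips inner selection).
#' @param params [KernelParams-class].
#' @param seed seed for fold assignment and molecule subsampling.
#' @return `data.frame` with columns `fraction`, `meanBitError`,
#'   `meanRelativeRank`.
#' @export
learningCurve <- function(world, fractions = c(0.2, 0.6, 1.0), k = 10L,
                          grid = 1, params = KernelParams(), seed = 1L) {
  spectra <- lapply(world$spectra, normalizeIntensities)
  K <- gramMatrix(spectra, params = params)@values
  fpS <- fingerprints(world$candidates)[world$moleculeOf, , drop = FALSE]
  folds <- makeGroupedFolds(world$moleculeOf, k, seed)
  fold <- unname(folds$fold)
  mols <- unique(unname(world$moleculeOf))
  molOrder <- .withSeed(seed + 1L, sample(mols))
  w <- rep(0.75, ncol(fpS))

  out <- lapply(sort(fractions), function(f) {
    errs <- numeric(0); rels <- numeric(0)
    for (fd in seq_len(folds$k)) {
      te <- which(fold == fd); pool <- which(fold != fd)
      poolMols <- molOrder[molOrder %in% unique(world$moleculeOf[pool])]
      selMols <- utils::head(poolMols, max(2, ceiling(f * length(poolMols))))
      tr <- pool[world$moleculeOf[pool] %in% selMols]
      pred <- .trainPredictBits(K, fpS, tr, te, grid)
      errs <- c(errs, mean(pred != fpS[te, , drop = FALSE]))
      for (ti in seq_along(te)) {
        r <- rankCandidates(world$candidates, pred[ti, ], w)
        rels <- c(rels, as.numeric(relativeRank(r, world$moleculeOf[te[ti]])))
      }
    }
    data.frame(fraction = f, meanBitError = mean(errs),
               meanRelativeRank = mean(rels))
  })
  do.call(rbind, out)
}

#' Pooled- versus single-energy training comparison
#'
#' Spectra of one molecule measured at different collision energies
#' fragment differently; this experiment asks whether pooling all energies
#' into one training set helps or hurts. A fixed fraction of molecules is
#' held out; their spectra at `testEnergy` form the test set. Two bit-SVM
#' banks are trained on the remaining molecules - one on `testEnergy`
#' spectra only, one on all energies pooled - and evaluated as mean bit
#' accuracy on the same held-out spectra.
#'
#' @param world a `ToyWorld` with `spectraPerMolecule >= 2`.
#' @param testEnergy which simulated energy forms the test set.
#' @param testFraction fraction of molecules held out.
#' @param grid SVM cost grid.
#' @param params [KernelParams-class].
#' @param seed seed for the molecule split.
#' @return Named numeric: `single`, `pooled` (mean bit accuracies).
#' @export
energyPoolingAccuracy <- function(world, testEnergy = 2L, testFraction = 0.2,
                                  grid = 1, params = KernelParams(),
                                  seed = 1L) {
  if (max(world$energyOf) < 2)
    stop("world must contain at least two collision energies")
  spectra <- lapply(world$spectra, normalizeIntensities)
  K <- gramMatrix(spectra, params = params)@values
  fpS <- fingerprints(world$candidates)[world$moleculeOf, , drop = FALSE]
  mols <- unique(unname(world$moleculeOf))
  testMols <- utils::head(.withSeed(seed, sample(mols)),
                          max(1, ceiling(testFraction * length(mols))))
  isTestMol <- world$moleculeOf %in% testMols
  te <- which(isTestMol & world$energyOf == testEnergy)
  trSingle <- which(!isTestMol & world$energyOf == testEnergy)
  trPooled <- which(!isTestMol)
  acc <- function(tr) {
    pred <- .trainPredictBits(K, fpS, tr, te, grid)
    mean(pred == fpS[te, , drop = FALSE])
  }
  c(single = acc(trSingle), pooled = acc(trPooled))
}
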