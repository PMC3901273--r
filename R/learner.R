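#' @include AllGenerics.R kernels.R
NULL

## Evaluate expr with a temporary RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Molecule-grouped cross-validation folds
#'
#' Multiple spectra of one molecule leak information across
#' cross-validation folds and inflate accuracy estimates. This assignment
#' therefore confines all spectra of a molecule to a single fold: the
#' distinct molecules are shuffled with the given seed and dealt
#' round-robin to the k folds, and every spectrum inherits its molecule's
#' fold.
#'
#' @param moleculeOf named character; spectrum identifier -> molecule
#'   identifier.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the molecule shuffle.
#' @return List of class `FoldAssignment` with elements `fold` (named
#'   integer per spectrum), `moleculeFold` (named integer per molecule),
#'   `k`, `seed`.
#' @export
makeGroupedFolds <- function(moleculeOf, k, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  molecules <- unique(unname(moleculeOf))
  if (length(molecules) < k)
    stop("fewer molecules (", length(molecules), ") than folds (", k, ")")
  shuffled <- .withSeed(seed, sample(molecules))
  ## deal molecules round-robin in shuffled order
  moleculeFold <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  fold <- moleculeFold[unname(moleculeOf)]
  names(fold) <- names(moleculeOf)
  structure(list(fold = fold, moleculeFold = moleculeFold,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "FoldAssignment")
}

#' Train a single fingerprint-bit SVM on a precomputed Gram matrix
#'
#' Solves the soft-margin kernel SVM dual for one ±1 bit and stores the
#' solution in a portable form: the products `alpha_i * y_i` over support
#' vectors, the support indices, and the bias, so that the decision value
#' on any spectrum is `sum_i alphaY_i K(chi_i, chi) + bias`. If the labels
#' are single-class no optimization is run; a constant model carrying that
#' class is returned (this keeps the predicted vector length stable across
#' folds).
#'
#' @param gram square numeric matrix (or [GramMatrix-class]) over the
#'   training spectra.
#' @param labels ±1 vector.
#' @param C soft-margin cost.
#' @param tol optimizer termination tolerance.
#' @return List with `constant`, `value`, `alphaY`, `support`, `bias`, `C`.
#' @export
trainBitSVM <- function(gram, labels, C = 1, tol = 1e-4) {
  K <- if (is(gram, "GramMatrix")) gram@values else gram
  if (nrow(K) != ncol(K)) stop("training requires a square Gram matrix")
  if (length(labels) != nrow(K)) stop("labels must match the Gram dimension")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(labels)) == 1L)
    return(list(constant = TRUE, value = labels[1], alphaY = numeric(0),
                support = integer(0), bias = 0, C = C))
  y <- factor(labels, levels = c(-1, 1))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C,
                       tol = tol)
  sv <- kernlab::SVindex(fit)
  alphaY <- unlist(kernlab::coef(fit))
  bias <- -kernlab::b(fit)
  ## kernlab's decision sign depends on internal label coding; calibrate
  ## against its own response predictions so that decision > 0 <=> +1.
  dec <- K[, sv, drop = FALSE] %*% alphaY + bias
  resp <- kernlab::predict(fit, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]))
  agree <- mean((dec > 0) == (resp == "1"))
  if (agree < 0.5) { alphaY <- -alphaY; bias <- -bias }
  list(constant = FALSE, value = NA_real_, alphaY = unname(alphaY),
       support = sv, bias = unname(bias), C = C)
}

## Decision values of a bit model on precomputed kernel columns
## kcols: matrix (n_eval x n_train) of kernel values against training spectra.
.bitDecision <- function(model, kcols) {
  if (model$constant) return(rep(model$value * Inf, nrow(kcols)))
  drop(kcols[, model$support, drop = FALSE] %*% model$alphaY) + model$bias
}

.signPlus <- function(x) ifelse(x >= 0, 1L, -1L)  # zero decision -> +1

#' Select the SVM cost C by grouped inner cross-validation
#'
#' Evaluates every grid value by molecule-grouped cross-validation inside
#' the training data and returns the value with the highest held-out
#' accuracy; ties are broken toward the smallest C (weakest regularization
#' of the margin, most conservative fit). The default grid is
#' `2^(-5:10)`.
#'
#' @param gram square Gram matrix (or [GramMatrix-class]) over the
#'   training spectra.
#' @param labels ±1 vector.
#' @param folds a `FoldAssignment` over the same spectra (see
#'   [makeGroupedFolds()]).
#' @param grid candidate C values.
#' @return The selected C.
#' @export
selectC <- function(gram, labels, folds, grid = 2^(-5:10)) {
  if (!length(grid)) stop("C grid must be non-empty")
  grid <- sort(grid)
  if (length(grid) == 1) return(grid)
  K <- if (is(gram, "GramMatrix")) gram@values else gram
  fold <- unname(folds$fold)
  acc <- vapply(grid, function(C) {
    correct <- 0L; total <- 0L
    for (f in unique(fold)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      m <- trainBitSVM(K[tr, tr, drop = FALSE], labels[tr], C)
      pred <- .signPlus(.bitDecision(m, K[te, tr, drop = FALSE]))
      correct <- correct + sum(pred == labels[te])
      total <- total + length(te)
    }
    correct / total
  }, numeric(1))
  grid[which.max(acc)]
}

#' Cross-validated per-bit reliability scores
#'
#' Runs the outer molecule-grouped cross-validation: for every fold, each
#' effective bit's SVM is trained on the fold complement (with C selected
#' by grouped inner cross-validation on that complement) and evaluated on
#' the held-out spectra. The reliability score `w_j` is the fraction of
#' held-out predictions matching the true bit, aggregated over all folds -
#' exactly the accuracy later used as the bit's observation probability in
#' Poisson-binomial candidate scoring. Bits that could be evaluated in no
#' fold receive the uninformative `w_j = 0.5`.
#'
#' @param gram square Gram matrix (or [GramMatrix-class]) over the
#'   training spectra.
#' @param fingerprintMatrix ±1 matrix (spectra x effective bits).
#' @param folds outer `FoldAssignment` (see [makeGroupedFolds()]).
#' @param moleculeOf named character; spectrum -> molecule, for the inner
#'   folds.
#' @param grid C grid for the inner selection.
#' @param innerK inner fold count (grouped; capped at the number of
#'   available training molecules).
#' @return Numeric vector of reliabilities in \[0, 1\], named by bit.
#' @export
crossValidatedReliability <- function(gram, fingerprintMatrix, folds,
                                      moleculeOf, grid = 2^(-5:10),
                                      innerK = 5L) {
  K <- if (is(gram, "GramMatrix")) gram@values else gram
  m <- ncol(fingerprintMatrix)
  fold <- unname(folds$fold)
  correct <- numeric(m); total <- numeric(m)
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te) || !length(tr)) next
    Ktr <- K[tr, tr, drop = FALSE]
    Kte <- K[te, tr, drop = FALSE]
    molTr <- moleculeOf[tr]
    kIn <- min(innerK, length(unique(molTr)))
    innerFolds <- if (kIn >= 2)
      makeGroupedFolds(stats::setNames(molTr, as.character(tr)), kIn,
                       seed = folds$seed + f) else NULL
    for (j in seq_len(m)) {
      yTr <- fingerprintMatrix[tr, j]
      model <- if (length(unique(yTr)) == 1L) {
        trainBitSVM(Ktr, yTr, C = grid[1])
      } else {
        C <- if (!is.null(innerFolds) && length(grid) > 1)
          selectC(Ktr, yTr, innerFolds, grid) else grid[1]
        trainBitSVM(Ktr, yTr, C)
      }
      pred <- .signPlus(.bitDecision(model, Kte))
      correct[j] <- correct[j] + sum(pred == fingerprintMatrix[te, j])
      total[j] <- total[j] + length(te)
    }
  }
  w <- ifelse(total > 0, correct / pmax(total, 1), 0.5)
  stats::setNames(w, colnames(fingerprintMatrix))
}

#' Train the full fingerprint-prediction model
#'
#' End-to-end training: intensity-normalizes the spectra, builds the
#' combined-kernel Gram matrix, removes ineffective fingerprint bits,
#' estimates per-bit reliability scores by molecule-grouped
#' cross-validation, then fits one final SVM per effective bit on all data
#' (C selected per bit by grouped inner cross-validation).
#'
#' @param spectra named list of [MassSpectrum-class] training spectra.
#' @param fingerprintMatrix ±1 matrix (spectra x all fingerprint keys),
#'   rows aligned with `spectra`, colnames = key names.
#' @param moleculeOf character; molecule identifier per spectrum (defaults
#'   to the spectra's `moleculeId` slots).
#' @param params [KernelParams-class].
#' @param k outer fold count (default 10).
#' @param innerK inner fold count for C selection (default 5).
#' @param grid C grid (default `2^(-5:10)`).
#' @param seed integer seed governing all fold shuffles.
#' @return A [FingerprintModel-class].
#' @export
trainFingerprintModel <- function(spectra, fingerprintMatrix,
                                  moleculeOf = NULL,
                                  params = KernelParams(), k = 10L,
                                  innerK = 5L, grid = 2^(-5:10), seed = 1L) {
  ids <- .spectrumIds(spectra)
  if (is.null(moleculeOf))
    moleculeOf <- vapply(spectra, moleculeId, character(1))
  if (anyNA(moleculeOf)) stop("every training spectrum needs a molecule id")
  if (nrow(fingerprintMatrix) != length(spectra))
    stop("fingerprintMatrix rows must align with the spectra")
  if (is.null(colnames(fingerprintMatrix)))
    stop("fingerprintMatrix must carry key names as colnames")
  moleculeOf <- stats::setNames(as.character(moleculeOf), ids)
  if (length(unique(moleculeOf)) < 2) stop("need spectra of at least 2 molecules")

  spectra <- lapply(spectra, normalizeIntensities)
  names(spectra) <- ids
  gram <- gramMatrix(spectra, params = params)
  mask <- effectiveBitMask(fingerprintMatrix)
  eff <- which(mask)
  if (!length(eff)) stop("no effective fingerprint bits in the training set")
  effFp <- fingerprintMatrix[, eff, drop = FALSE]

  folds <- makeGroupedFolds(moleculeOf, min(k, length(unique(moleculeOf))),
                            seed = seed)
  reliability <- crossValidatedReliability(gram, effFp, folds, moleculeOf,
                                           grid = grid, innerK = innerK)

  finalFolds <- if (length(grid) > 1)
    makeGroupedFolds(moleculeOf, min(innerK, length(unique(moleculeOf))),
                     seed = seed + 1000L) else NULL
  K <- gram@values
  bitModels <- lapply(seq_along(eff), function(jj) {
    y <- effFp[, jj]
    C <- if (!is.null(finalFolds)) selectC(K, y, finalFolds, grid) else grid[1]
    m <- trainBitSVM(K, y, C)
    m$bitIndex <- eff[jj]
    m
  })

  new("FingerprintModel",
      version = "1",
      kernelParams = params,
      keyNames = colnames(fingerprintMatrix),
      mask = as.vector(mask),
      reliability = unname(reliability),
      bitModels = bitModels,
      trainingSpectra = spectra,
      trainingIds = ids,
      moleculeOf = unname(moleculeOf),
      selfSim = .selfSimilarities(spectra, params),
      schemaHash = fingerprintSchemaHash(colnames(fingerprintMatrix)),
      seed = as.integer(seed))
}

## Combined normalized kernel vector between one query and the model's
## training spectra; same variant averaging as gramMatrix().
.queryKernelVector <- function(object, query) {
  params <- object@kernelParams
  vs <- params@variants
  query <- normalizeIntensities(query)
  qPeaks <- lapply(stats::setNames(vs, vs), function(v) .variantPeaks(query, v))
  sm <- params@sigmaMass; si <- params@sigmaIntensity
  qSelf <- vapply(vs, function(v) .rawKernel(qPeaks[[v]], qPeaks[[v]], sm, si),
                  numeric(1))
  n <- length(object@trainingSpectra)
  kvec <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (v in vs) {
      raw <- .rawKernel(.variantPeaks(object@trainingSpectra[[i]], v),
                        qPeaks[[v]], sm, si)
      tot <- tot + if (params@normalize)
        raw / sqrt(object@selfSim[i, v] * qSelf[[v]]) else raw
    }
    kvec[i] <- tot / length(vs)
  }
  kvec
}

#' @rdname predictFingerprints
#' @export
setMethod("predictFingerprints", "FingerprintModel", function(object, query) {
  eff <- which(object@mask)
  out <- integer(length(eff))
  names(out) <- object@keyNames[eff]
  allConstant <- all(vapply(object@bitModels, `[[`, logical(1), "constant"))
  if (allConstant) {
    out[] <- vapply(object@bitModels, function(m) as.integer(m$value), integer(1))
  } else {
    kvec <- matrix(.queryKernelVector(object, query), nrow = 1)
    for (jj in seq_along(object@bitModels)) {
      m <- object@bitModels[[jj]]
      out[jj] <- if (m$constant) as.integer(m$value)
                 else .signPlus(.bitDecision(m, kvec))
    }
  }
  attr(out, "schemaHash") <- object@schemaHash
  out
})
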