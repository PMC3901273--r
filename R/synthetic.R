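#' @include AllGenerics.R isotopes.R
NULL

## Monoisotopic mass of a formula from the lightest isotopes.
.monoisotopicMass <- function(formula, table = isotopeTable()) {
  counts <- parseFormula(formula)
  sum(vapply(names(counts), function(el) {
    if (is.null(table[[el]])) stop("unknown element symbol '", el, "'")
    table[[el]]$mass[1] * counts[[el]]
  }, numeric(1)))
}

#' Generate a synthetic identification world with known ground truth
#'
#' Builds a self-contained toy problem for exercising the whole pipeline:
#' molecules with ±1 fingerprints and formula-derived exact masses, and
#' fragment spectra in which every +1 fingerprint bit plants a
#' characteristic fragment peak at a bit-specific mass. Bits are therefore
#' statistically learnable from the spectra by construction - the
#' generator is a statistical stand-in for fragmentation chemistry, not a
#' fragmenter.
#'
#' Specifics:
#' \itemize{
#'   \item bit masses are spread over 60-150 Da with >1 Da spacing, far
#'     apart relative to the kernel's mass sigma;
#'   \item each bit's +1 fraction is drawn in \[0.3, 0.7\], so all bits
#'     survive the effective-bit mask; duplicated fingerprint rows are
#'     perturbed until all molecules are unique;
#'   \item each molecule gets a random CHNO formula whose monoisotopic
#'     mass (from the embedded isotope table) is its exact mass, and
#'     `peaksPerMolecule` uninformative decoy fragment masses;
#'   \item `spectraPerMolecule` spectra per molecule emulate different
#'     collision energies by independent random subsets of the planted and
#'     decoy peaks; peak masses get Gaussian jitter of sd `massJitterSd`
#'     and intensities a log-normal jitter;
#'   \item regeneration with the same seed is bit-identical, and the
#'     global RNG state is left untouched.
#' }
#'
#' @param nMolecules number of molecules (>= 2).
#' @param mBits number of fingerprint bits (>= 2).
#' @param peaksPerMolecule number of decoy (non-bit) fragment peaks per
#'   molecule.
#' @param massJitterSd Gaussian mass jitter sd in Da (default 0.003).
#' @param intensityJitterSd sd of the log-normal intensity jitter.
#' @param spectraPerMolecule simulated collision energies per molecule.
#' @param seed integer seed.
#' @return List of class `ToyWorld`: `candidates` ([CandidateSet-class]),
#'   `spectra` (named list of [MassSpectrum-class]), `moleculeOf`,
#'   `energyOf`, `bitMasses`, `seed`.
#' @export
generateToyWorld <- function(nMolecules = 100, mBits = 20,
                             peaksPerMolecule = 5, massJitterSd = 0.003,
                             intensityJitterSd = 0.1,
                             spectraPerMolecule = 2, seed = 1L) {
  if (nMolecules < 2 || mBits < 2)
    stop("need at least 2 molecules and 2 fingerprint bits")
  .withSeed(seed, {
    bitMasses <- seq(60, 150, length.out = mBits) +
      stats::runif(mBits, -0.3, 0.3)
    keyNames <- sprintf("BIT_%03d", seq_len(mBits))
    molIds <- sprintf("TOY%04d", seq_len(nMolecules))

    fp <- matrix(-1L, nMolecules, mBits, dimnames = list(molIds, keyNames))
    for (j in seq_len(mBits)) {
      nPos <- max(1L, min(nMolecules - 1L,
                          round(nMolecules * stats::runif(1, 0.3, 0.7))))
      fp[sample(nMolecules, nPos), j] <- 1L
    }
    ## every molecule needs at least one positive bit (one planted peak)
    none <- which(rowSums(fp == 1L) == 0)
    for (i in none) fp[i, sample(mBits, 1)] <- 1L
    ## enforce unique fingerprints by flipping random bits of duplicates
    repeat {
      dup <- which(duplicated(apply(fp, 1, paste, collapse = "")) |
                     rowSums(fp == 1L) == 0)
      if (!length(dup)) break
      for (i in dup) {
        j <- sample(mBits, 1)
        fp[i, j] <- -fp[i, j]
      }
    }

    formulas <- character(nMolecules)
    exactMass <- numeric(nMolecules)
    for (i in seq_len(nMolecules)) {
      cN <- sample(14:28, 1)
      hN <- round(cN * 1.6) + sample(0:3, 1)
      nN <- sample(0:3, 1)
      oN <- sample(1:6, 1)
      formulas[i] <- paste0("C", cN, "H", hN,
                            if (nN > 0) paste0("N", nN) else "",
                            "O", oN)
      exactMass[i] <- .monoisotopicMass(formulas[i])
    }

    decoyMasses <- matrix(stats::runif(nMolecules * peaksPerMolecule, 60, 150),
                          nMolecules, max(peaksPerMolecule, 1))

    spectra <- list(); moleculeOf <- character(0); energyOf <- integer(0)
    for (i in seq_len(nMolecules)) {
      planted <- bitMasses[fp[i, ] == 1L]
      decoys <- if (peaksPerMolecule > 0) decoyMasses[i, ] else numeric(0)
      for (e in seq_len(spectraPerMolecule)) {
        keepP <- stats::runif(length(planted)) < 0.85
        if (!any(keepP)) keepP[sample.int(length(planted), 1)] <- TRUE
        keepD <- stats::runif(length(decoys)) < 0.6
        mz <- c(planted[keepP], decoys[keepD])
        base <- c(abs(stats::rnorm(sum(keepP), 1, 0.25)) + 0.1,
                  abs(stats::rnorm(sum(keepD), 0.25, 0.1)) + 0.02)
        mz <- mz + stats::rnorm(length(mz), 0, massJitterSd)
        ints <- base * exp(stats::rnorm(length(base), 0, intensityJitterSd))
        sid <- sprintf("%s_E%d", molIds[i], e)
        spectra[[sid]] <- MassSpectrum(
          mz, ints, precursorMz = exactMass[i] + fmsConstants$protonMass,
          msLevel = 2L, ionMode = "positive",
          instrument = sprintf("TOY-ESI-QTOF-CID-E%d", e),
          moleculeId = molIds[i])
        moleculeOf <- c(moleculeOf, molIds[i])
        energyOf <- c(energyOf, e)
      }
    }
    names(moleculeOf) <- names(spectra)
    names(energyOf) <- names(spectra)
    structure(list(
      candidates = CandidateSet(molIds, exactMass, fp, formula = formulas),
      spectra = spectra,
      moleculeOf = moleculeOf,
      energyOf = energyOf,
      bitMasses = bitMasses,
      seed = as.integer(seed)
    ), class = "ToyWorld")
  })
}

#' @export
print.ToyWorld <- function(x, ...) {
  cat(sprintf("ToyWorld (seed %d): %d molecules, %d spectra, %d bits\n",
              x$seed, length(x$candidates), length(x$spectra),
              length(x$bitMasses)))
  invisible(x)
}

#' Corrupt a fingerprint at known per-bit reliability
#'
#' Simulates a fingerprint predictor of known accuracy: bit j of `y` is
#' flipped independently with probability `1 - w[j]`. This isolates the
#' retrieval layer - the Poisson-binomial scorer can be tested against
#' predictions whose error rates are exactly the reliabilities it assumes.
#'
#' @param y ±1 fingerprint vector.
#' @param w reliabilities in \[0, 1\]; recycled over bits.
#' @param seed integer seed.
#' @return ±1 vector of the same length.
#' @export
corruptFingerprints <- function(y, w, seed = 1L) {
  w <- rep_len(w, length(y))
  .withSeed(seed, {
    flip <- stats::runif(length(y)) < (1 - w)
    y[flip] <- -y[flip]
    y
  })
}

#' Relative rank of the true molecule in a ranked list
#'
#' The retrieval quality metric: `rank(trueId) / n`, in (0, 1], lower is
#' better. If the true molecule is absent from the list (e.g. pruned by
#' the mass window) the sentinel value 1.0 is returned with attribute
#' `found = FALSE` and a warning.
#'
#' @param result ranking from [rankCandidates()].
#' @param trueId identifier of the correct molecule.
#' @return numeric in (0, 1] with attribute `found`.
#' @export
relativeRank <- function(result, trueId) {
  pos <- match(trueId, result$moleculeId)
  if (is.na(pos)) {
    warning("true molecule '", trueId, "' is not in the ranked list")
    return(structure(1.0, found = FALSE))
  }
  structure(result$rank[pos] / nrow(result), found = TRUE)
}

#' Export a toy world in the formats the real pipeline reads
#'
#' Writes `spectra.massbank` (MassBank records; accession = spectrum id,
#' CH$NAME = molecule id) and `candidates.tsv` (precomputed candidate
#' table) into `dir`, so synthetic fixtures exercise the production
#' parsers.
#'
#' @param world a `ToyWorld`.
#' @param dir output directory.
#' @return Named character vector of the two file paths.
#' @export
exportToyWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specPath <- file.path(dir, "spectra.massbank")
  recs <- vapply(names(world$spectra), function(id)
    writeMassBankRecord(world$spectra[[id]], accession = id), character(1))
  writeLines(paste(recs, collapse = "\n"), specPath)
  dbPath <- file.path(dir, "candidates.tsv")
  writeCandidateTable(world$candidates, dbPath)
  c(spectra = specPath, candidates = dbPath)
}
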