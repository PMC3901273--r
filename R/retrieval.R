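#' @include AllGenerics.R
NULL

#' Filter a candidate database by a ppm mass window
#'
#' Keeps the molecules whose exact mass lies within `mass * ppm * 1e-6` Da
#' of the query mass, i.e. `|exactMass - mass| / mass * 1e6 <= ppm`. An
#' empty result is allowed: a narrow window simply risks excluding the
#' true molecule when the mass estimate is off.
#'
#' @param candidates a [CandidateSet-class].
#' @param mass query neutral mass in Da (> 0).
#' @param ppm window half-width in parts per million (>= 0).
#' @return A [CandidateSet-class] subset.
#' @export
massWindowFilter <- function(candidates, mass, ppm) {
  if (ppm < 0) stop("ppm must be non-negative")
  if (mass <= 0) stop("mass must be positive")
  delta <- mass * ppm * 1e-6
  keep <- abs(candidates@exactMass - mass) <= delta
  candidates[which(keep)]
}

#' Poisson-binomial log-likelihood of a candidate fingerprint
#'
#' Scores how likely the candidate's true fingerprint `y` is to have
#' generated the predicted fingerprint `yhat`, treating each bit as an
#' independent observation with accuracy `w_j` (the bit's cross-validated
#' reliability): agreement contributes `log(w_j)`, disagreement
#' `log(1 - w_j)`. Reliabilities are clipped into `[eps, 1 - eps]` so a
#' perfectly (un)reliable bit cannot produce an infinite log-score. Scores
#' are kept in log space because products over hundreds of bits underflow.
#'
#' For fixed `y`, `exp` of the scores sums to one over the space of all
#' possible `yhat` vectors - the score is a proper likelihood.
#'
#' @param y candidate (database) fingerprint, ±1.
#' @param yhat predicted fingerprint, ±1, same length.
#' @param w reliability scores in \[0, 1\], one per bit.
#' @param eps clipping constant (default 1e-6).
#' @return numeric log-likelihood (<= 0).
#' @export
poissonBinomialLogScore <- function(y, yhat, w, eps = 1e-6) {
  if (length(y) != length(yhat)) stop("fingerprint length mismatch")
  if (length(w) != length(y)) stop("one reliability score per bit required")
  w <- pmin(pmax(w, eps), 1 - eps)
  sum(ifelse(y == yhat, log(w), log1p(-w)))
}

#' Rank candidates by fingerprint likelihood
#'
#' Scores every candidate with [poissonBinomialLogScore()] against the
#' predicted fingerprint and sorts in decreasing score order. Identical
#' fingerprints give identical scores; ties receive distinct consecutive
#' ranks, broken deterministically by ascending molecule identifier.
#'
#' @param candidates a [CandidateSet-class]; fingerprint columns must match
#'   `yhat`.
#' @param yhat predicted ±1 fingerprint over the same keys.
#' @param w per-bit reliability scores.
#' @param queryId identifier attached to the result.
#' @return `data.frame` with columns `rank`, `moleculeId`, `exactMass`,
#'   `formula`, `logScore` (attribute `queryId`); zero rows for an empty
#'   candidate set.
#' @export
rankCandidates <- function(candidates, yhat, w, queryId = NA_character_) {
  n <- length(candidates)
  if (n == 0) {
    out <- data.frame(rank = integer(0), moleculeId = character(0),
                      exactMass = numeric(0), formula = character(0),
                      logScore = numeric(0))
    attr(out, "queryId") <- queryId
    return(out)
  }
  fp <- candidates@fingerprints
  if (ncol(fp) != length(yhat))
    stop("candidate fingerprints and prediction differ in length")
  eps <- 1e-6
  wc <- pmin(pmax(w, eps), 1 - eps)
  ## vectorized per-bit contributions: log(w) on agreement, log(1-w) otherwise
  agree <- fp == matrix(yhat, n, length(yhat), byrow = TRUE)
  contrib <- matrix(log1p(-wc), n, length(wc), byrow = TRUE)
  contrib[agree] <- matrix(log(wc), n, length(wc), byrow = TRUE)[agree]
  scores <- rowSums(contrib)
  o <- order(-scores, candidates@ids)
  out <- data.frame(rank = seq_len(n),
                    moleculeId = candidates@ids[o],
                    exactMass = candidates@exactMass[o],
                    formula = candidates@formula[o],
                    logScore = scores[o],
                    stringsAsFactors = FALSE)
  attr(out, "queryId") <- queryId
  out
}

#' Fingerprint-uniqueness statistics of a database
#'
#' Many distinct molecules share a fingerprint vector, which inflates
#' candidate lists. This utility groups the database by identical
#' fingerprint vector and reports the duplicate count `N_dp` per molecule
#' (the size of its fingerprint group), the fraction of molecules with a
#' unique fingerprint, and the fraction with a unique (fingerprint, exact
#' mass) pair - mass often disambiguates molecules that fingerprints
#' cannot.
#'
#' @param candidates a non-empty [CandidateSet-class].
#' @return List with `table` (`data.frame` of `N_dp` and `nMolecules`: how
#'   many molecules have that duplicate count), `uniqueFingerprintFraction`
#'   and `uniqueFingerprintMassFraction`.
#' @export
fingerprintUniquenessStats <- function(candidates) {
  n <- length(candidates)
  if (n == 0) stop("empty candidate set")
  key <- apply(candidates@fingerprints, 1, paste, collapse = "")
  sizes <- table(key)
  ndpPerMol <- as.integer(sizes[key])
  tab <- as.data.frame(table(ndpPerMol), stringsAsFactors = FALSE)
  names(tab) <- c("N_dp", "nMolecules")
  tab$N_dp <- as.integer(tab$N_dp)
  keyMass <- paste(key, sprintf("%.6f", candidates@exactMass))
  sizesMass <- table(keyMass)
  list(table = tab,
       uniqueFingerprintFraction = mean(ndpPerMol == 1L),
       uniqueFingerprintMassFraction = mean(as.integer(sizesMass[keyMass]) == 1L))
}
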