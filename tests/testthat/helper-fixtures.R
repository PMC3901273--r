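## Shared fixtures and independent oracles.

## Random MS/MS spectrum with a precursor above all fragments.
randomSpectrum <- function(n = 5, precursor = 300, msLevel = 2L) {
  MassSpectrum(runif(n, 50, precursor - 20), runif(n, 0.05, 1),
               precursorMz = precursor, msLevel = msLevel,
               ionMode = "positive")
}

## Independent numerical-quadrature oracle for the peak-pair Gaussian
## product integral. The 2-D integrand factorizes over the mass and
## intensity axes (diagonal covariance), so the double integral is
## evaluated as the product of two adaptive 1-D quadratures.
quadPeakIntegral <- function(m1, i1, m2, i2, sm, si) {
  axis <- function(a, b, s) {
    stats::integrate(function(x) dnorm(x, a, s) * dnorm(x, b, s),
                     min(a, b) - 12 * s, max(a, b) + 12 * s,
                     rel.tol = 1e-12, abs.tol = 0)$value
  }
  axis(m1, m2, sm) * axis(i1, i2, si)
}

## Brute-force probability product kernel over two peak matrices:
## explicit double loop, no vectorization shared with the implementation.
brutePeaksKernel <- function(P1, P2, params) {
  total <- 0
  for (a in seq_len(nrow(P1)))
    for (b in seq_len(nrow(P2)))
      total <- total + peakPairIntegral(P1[a, 1], P1[a, 2],
                                        P2[b, 1], P2[b, 2], params)
  unname(total) / (nrow(P1) * nrow(P2))
}

## Pairwise-difference pseudo-peaks built independently of the package.
bruteDiffPeaks <- function(P) {
  out <- NULL
  n <- nrow(P)
  for (a in seq_len(n - 1))
    for (b in seq((a + 1), n))
      out <- rbind(out, c(P[b, 1] - P[a, 1], P[a, 2] * P[b, 2]))
  colnames(out) <- c("mass", "intensity")
  out
}

## Linear-kernel toy classification problem on 2-D points, one "molecule"
## per point; labels = side of the x-axis, separable with margin.
linearToyGram <- function(n = 24, margin = 0.5, seed = 42) {
  set.seed(seed)
  x1 <- c(runif(n / 2, margin, 2), runif(n / 2, -2, -margin))
  x2 <- runif(n, -1, 1)
  X <- cbind(x1, x2, 1)  # affine feature so a bias is learnable
  list(K = tcrossprod(X), labels = ifelse(x1 > 0, 1, -1),
       moleculeOf = stats::setNames(sprintf("mol%02d", seq_len(n)),
                                    sprintf("s%02d", seq_len(n))))
}

## Exhaustive isotopologue enumeration for a small formula: every atom
## independently takes one of its element's isotopes.
bruteMoleculePattern <- function(formula, table = isotopeTable()) {
  counts <- parseFormula(formula)
  mass <- 0; ab <- 1
  for (el in names(counts)) {
    entry <- table[[el]]
    for (dummy in seq_len(counts[[el]])) {
      mass <- outer(mass, entry$mass, "+")
      ab <- outer(ab, entry$abundance, "*")
    }
  }
  df <- aggregate(ab ~ mass,
                  data = data.frame(mass = round(as.numeric(mass), 6),
                                    ab = as.numeric(ab)), FUN = sum)
  df[order(df$mass), ]
}

## Toy candidate set with handcrafted fingerprints over named keys.
toyCandidates <- function(fpRows, masses = NULL, ids = NULL) {
  n <- nrow(fpRows)
  if (is.null(ids)) ids <- sprintf("M%02d", seq_len(n))
  if (is.null(masses)) masses <- seq(200, 200 + n - 1)
  if (is.null(colnames(fpRows)))
    colnames(fpRows) <- sprintf("BIT_%03d", seq_len(ncol(fpRows)))
  rownames(fpRows) <- NULL
  CandidateSet(ids, masses, fpRows)
}
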