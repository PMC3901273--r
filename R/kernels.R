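#' @include AllGenerics.R
NULL

#' Kernel parameter constructor
#'
#' The probability product kernel models every observed peak as a 2-D
#' Gaussian centred at the measurement `(mass, intensity)` with a diagonal
#' covariance `diag(sigmaMass^2, sigmaIntensity^2)` shared by all peaks; a
#' spectrum is the uniform mixture of its peak Gaussians. `sigmaMass`
#' should reflect the instrument's mass accuracy (0.01 Da is a sensible
#' high-resolution default; ~0.5 Da for nominal-mass instruments);
#' `sigmaIntensity` is on the sum-to-one intensity scale (default 0.05).
#'
#' @param sigmaMass mass standard deviation in Da.
#' @param sigmaIntensity intensity standard deviation (relative units).
#' @param variants subset of `c("peaks", "mloss", "diff")`; the default
#'   `peaks + mloss` combination is the recommended general-purpose choice.
#' @param normalize cosine-normalize each variant kernel before summing.
#' @return A [KernelParams-class].
#' @examples
#' KernelParams(sigmaMass = 0.01, variants = c("peaks", "mloss"))
#' @export
KernelParams <- function(sigmaMass = 0.01, sigmaIntensity = 0.05,
                         variants = c("peaks", "mloss"), normalize = TRUE) {
  new("KernelParams", sigmaMass = sigmaMass, sigmaIntensity = sigmaIntensity,
      variants = unique(variants), normalize = normalize)
}

#' Closed-form integral of a product of two peak Gaussians
#'
#' For peaks p1, p2 modelled as 2-D Gaussians with the shared diagonal
#' covariance `Sigma = diag(sigma_m^2, sigma_i^2)`, the integral
#' `int N(x; p1, Sigma) N(x; p2, Sigma) dx` has the closed form
#' `N(p1 - p2; 0, 2 Sigma)`, i.e.
#' `exp(-(dm^2/(4 sigma_m^2) + di^2/(4 sigma_i^2))) / (4 pi sigma_m sigma_i)`.
#' The value is strictly positive, symmetric in its arguments, and equals
#' `1/(4 pi sigma_m sigma_i)` when the peaks coincide.
#'
#' @param mass1,intensity1 first peak.
#' @param mass2,intensity2 second peak.
#' @param params a [KernelParams-class] supplying the sigmas.
#' @return numeric scalar (vectorized over peaks).
#' @examples
#' p <- KernelParams(sigmaMass = 0.01, sigmaIntensity = 0.1)
#' peakPairIntegral(100, 0.5, 100, 0.5, p)  # 1 / (4 * pi * 0.01 * 0.1)
#' @export
peakPairIntegral <- function(mass1, intensity1, mass2, intensity2, params) {
  validObject(params)
  sm <- params@sigmaMass; si <- params@sigmaIntensity
  dm <- mass1 - mass2; di <- intensity1 - intensity2
  exp(-(dm * dm) / (4 * sm * sm) - (di * di) / (4 * si * si)) / (4 * pi * sm * si)
}

## Raw (unnormalized) probability product kernel between two peak matrices:
## uniform mixture weights give the 1/(l * l') prefactor.
.rawKernel <- function(P1, P2, sm, si) {
  dm <- outer(P1[, 1], P2[, 1], "-")
  di <- outer(P1[, 2], P2[, 2], "-")
  sum(exp(-(dm * dm) / (4 * sm * sm) - (di * di) / (4 * si * si))) /
    (4 * pi * sm * si * nrow(P1) * nrow(P2))
}

#' Mass-loss transform of a spectrum
#'
#' Maps every fragment peak `(mu, iota)` to the neutral-loss peak
#' `(mu_prec - mu, iota)`, encoding the mass cleaved off the precursor. A
#' fragment at the precursor mass maps to a loss of zero (represented at a
#' tiny positive epsilon so the peak is retained). Fragments heavier than
#' the precursor would give negative losses - they indicate adduct or
#' isotope peaks above the assumed precursor and are dropped with a
#' warning. Applying the transform twice recovers the original masses.
#'
#' @param spectrum a [MassSpectrum-class] with a precursor m/z.
#' @return A [MassSpectrum-class] of loss peaks (sorted by loss mass).
#' @export
lossSpectrum <- function(spectrum) {
  prec <- precursorMz(spectrum)
  if (is.na(prec))
    stop("mass-loss transform requires a precursor m/z (spectrum '",
         spectrum@moleculeId, "')")
  p <- peakMatrix(spectrum)
  loss <- prec - p[, 1]
  neg <- loss < 0
  if (any(neg)) {
    warning(sum(neg), " peak(s) above the precursor mass dropped in mass-loss transform")
    loss <- loss[!neg]; ints <- p[!neg, 2]
  } else ints <- p[, 2]
  if (!length(loss)) stop("no peaks remain after the mass-loss transform")
  loss[loss == 0] <- .Machine$double.eps  # class requires positive masses
  MassSpectrum(loss, ints, precursorMz = prec, msLevel = msLevel(spectrum),
               ionMode = ionMode(spectrum), instrument = instrumentTag(spectrum),
               moleculeId = moleculeId(spectrum))
}

## Pseudo-spectrum of all pairwise peak differences (ordered pairs i < j):
## pseudo-peak at (mu_j - mu_i, iota_i * iota_j).
.diffPeaks <- function(P) {
  n <- nrow(P)
  if (n < 2)
    stop("the mass-difference kernel needs at least two peaks")
  pairs <- utils::combn(n, 2)
  dm <- P[pairs[2, ], 1] - P[pairs[1, ], 1]
  di <- P[pairs[1, ], 2] * P[pairs[2, ], 2]
  cbind(mass = dm, intensity = di)
}

.variantPeaks <- function(spectrum, variant) {
  switch(variant,
    peaks = peakMatrix(spectrum),
    mloss = peakMatrix(lossSpectrum(spectrum)),
    diff  = .diffPeaks(peakMatrix(spectrum)),
    stop("unknown kernel variant '", variant, "'"))
}

#' Probability product kernel between two spectra
#'
#' Evaluates one raw (unnormalized) kernel variant between two spectra.
#' Each spectrum is the uniform mixture of 2-D Gaussians over its peaks, so
#' the kernel is the all-against-all sum of [peakPairIntegral()] values
#' divided by the product of peak counts. Variants differ in the peak
#' representation:
#' \describe{
#'   \item{peaks}{the peaks themselves;}
#'   \item{mloss}{neutral losses relative to the precursor
#'     (see [lossSpectrum()]);}
#'   \item{diff}{all pairwise peak differences (`mu_j - mu_i` for `i < j`,
#'     with intensity `iota_i * iota_j`), a precursor-free generalization of
#'     the loss representation with quadratically more pseudo-peaks.}
#' }
#'
#' @param s1,s2 [MassSpectrum-class] objects (non-empty).
#' @param variant one of `"peaks"`, `"mloss"`, `"diff"`.
#' @param params a [KernelParams-class].
#' @return positive numeric scalar; symmetric in `s1`, `s2`.
#' @export
kernelValue <- function(s1, s2, variant = "peaks", params = KernelParams()) {
  validObject(params)
  if (nPeaks(s1) == 0 || nPeaks(s2) == 0)
    stop("kernel values are undefined for empty spectra")
  P1 <- .variantPeaks(s1, variant)
  P2 <- .variantPeaks(s2, variant)
  .rawKernel(P1, P2, params@sigmaMass, params@sigmaIntensity)
}

#' Normalize and combine kernel variant values
#'
#' Applies cosine normalization `K(x, y) / sqrt(K(x, x) K(y, y))` per
#' variant (when `params@normalize` is `TRUE`) and sums the variants in
#' `params@variants` with unit weights. Raw kernel values scale with
#' `1/(sigma_m sigma_i)` and with peak counts; normalization puts every
#' variant on the common (0, 1] scale so the sum is balanced.
#'
#' @param values named numeric; raw cross-kernel value per variant.
#' @param self1,self2 named numeric; raw self-similarities of the two
#'   spectra per variant (must be positive).
#' @param params a [KernelParams-class].
#' @return numeric scalar in `(0, length(variants)]` when normalized.
#' @export
normalizeAndCombine <- function(values, self1, self2, params) {
  vs <- params@variants
  if (!all(vs %in% names(values)) || !all(vs %in% names(self1)) ||
      !all(vs %in% names(self2)))
    stop("values/self1/self2 must be named by the kernel variants")
  total <- 0
  for (v in vs) {
    if (params@normalize) {
      denom <- sqrt(self1[[v]] * self2[[v]])
      if (!is.finite(denom) || denom <= 0)
        stop("zero self-similarity in variant '", v, "'; cannot normalize")
      total <- total + values[[v]] / denom
    } else {
      total <- total + values[[v]]
    }
  }
  unname(total)
}

.spectrumIds <- function(spectra) {
  ids <- names(spectra)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("spectrum_%03d", seq_along(spectra))
  if (anyDuplicated(ids)) stop("spectrum identifiers must be unique")
  ids
}

## Raw self-similarity matrix: one row per spectrum, one column per variant.
.selfSimilarities <- function(spectra, params) {
  vs <- params@variants
  out <- matrix(NA_real_, length(spectra), length(vs),
                dimnames = list(NULL, vs))
  for (i in seq_along(spectra)) {
    for (v in vs)
      out[i, v] <- kernelValue(spectra[[i]], spectra[[i]], v, params)
  }
  out
}

#' Gram matrix over lists of spectra
#'
#' Batch evaluation of the combined (normalized) kernel: entry (i, j) is
#' [normalizeAndCombine()] over the variant kernel values between `rows[[i]]`
#' and `cols[[j]]`, divided by the number of variants, i.e. the uniform
#' average of the per-variant (normalized) kernels. Averaging rather than
#' summing keeps the diagonal of a normalized square Gram at exactly one
#' whatever the variant set; positive semidefiniteness is unaffected. With
#' `cols = NULL` the square Gram over `rows` is computed exploiting
#' symmetry; the result is then symmetric and PSD up to numerical
#' tolerance.
#'
#' @param rows list of [MassSpectrum-class]; names become row identifiers.
#' @param cols optional second list (cross-Gram); `NULL` for the square case.
#' @param params a [KernelParams-class].
#' @return A [GramMatrix-class].
#' @export
gramMatrix <- function(rows, cols = NULL, params = KernelParams()) {
  validObject(params)
  rowIds <- .spectrumIds(rows)
  square <- is.null(cols)
  if (square) { cols <- rows; colIds <- rowIds } else colIds <- .spectrumIds(cols)
  vs <- params@variants

  rowPeaks <- lapply(rows, function(s) lapply(stats::setNames(vs, vs),
                                              function(v) .variantPeaks(s, v)))
  colPeaks <- if (square) rowPeaks
              else lapply(cols, function(s) lapply(stats::setNames(vs, vs),
                                                   function(v) .variantPeaks(s, v)))
  sm <- params@sigmaMass; si <- params@sigmaIntensity
  selfOf <- function(pk) vapply(vs, function(v) .rawKernel(pk[[v]], pk[[v]], sm, si),
                                numeric(1))
  selfRow <- lapply(rowPeaks, selfOf)
  selfCol <- if (square) selfRow else lapply(colPeaks, selfOf)

  K <- matrix(0, length(rows), length(cols))
  for (i in seq_along(rows)) {
    jstart <- if (square) i else 1L
    for (j in seq(jstart, length(cols))) {
      vals <- vapply(vs, function(v)
        .rawKernel(rowPeaks[[i]][[v]], colPeaks[[j]][[v]], sm, si), numeric(1))
      kij <- tryCatch(
        normalizeAndCombine(vals, selfRow[[i]], selfCol[[j]], params),
        error = function(e) stop("kernel failure for pair (", rowIds[i], ", ",
                                 colIds[j], "): ", conditionMessage(e)))
      kij <- kij / length(vs)
      K[i, j] <- kij
      if (square) K[j, i] <- kij
    }
  }
  new("GramMatrix", values = K, rowIds = rowIds, colIds = colIds, params = params)
}

#' Write / read a Gram matrix as tab-separated text
#'
#' Dense numeric matrix with a row/column identifier header, making trained
#' models portable across machines.
#'
#' @param gram a [GramMatrix-class].
#' @param path file path.
#' @return `readGramMatrix` returns a [GramMatrix-class] (kernel parameters
#'   restored from the header comment).
#' @export
writeGramMatrix <- function(gram, path) {
  p <- gram@params
  hdr <- sprintf("# sigmaMass=%.12g sigmaIntensity=%.12g variants=%s normalize=%s",
                 p@sigmaMass, p@sigmaIntensity,
                 paste(p@variants, collapse = ","), p@normalize)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("id", gram@colIds), collapse = "\t"), con)
  for (i in seq_along(gram@rowIds))
    writeLines(paste(c(gram@rowIds[i], sprintf("%.15g", gram@values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeGramMatrix
#' @export
readGramMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  opts <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  params <- KernelParams(sigmaMass = as.numeric(opts[["sigmaMass"]]),
                         sigmaIntensity = as.numeric(opts[["sigmaIntensity"]]),
                         variants = strsplit(opts[["variants"]], ",")[[1]],
                         normalize = as.logical(opts[["normalize"]]))
  colIds <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  rowIds <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(colIds))))
  if (length(colIds) == 1) vals <- matrix(as.numeric(vals), ncol = 1)
  new("GramMatrix", values = vals, rowIds = rowIds, colIds = colIds,
      params = params)
}

#' Estimate peak measurement variances from replicate spectra
#'
#' The kernel's Gaussian peak model needs the measurement standard
#' deviations of mass and intensity. Given groups of replicate spectra of
#' the same molecule (and collision energy), peaks of each replicate are
#' greedily matched to the peaks of the group's first spectrum within a
#' coarse mass tolerance; the pooled within-cluster variances of matched
#' masses and intensities estimate `sigma_m^2` and `sigma_i^2`. Estimates
#' are floored (defaults 1e-4 Da and 1e-3) so that identical replicates do
#' not produce a degenerate kernel. Intensities are sum-normalized before
#' matching so the intensity scale agrees with the kernel's.
#'
#' @param replicateGroups list of lists of [MassSpectrum-class]; each inner
#'   list holds replicates of one molecule/energy (>= 2 spectra to
#'   contribute).
#' @param matchTol coarse mass tolerance in Da for matching peaks (0.5).
#' @param floorMass,floorIntensity lower bounds for the returned sigmas.
#' @return Named numeric: `sigmaMass`, `sigmaIntensity`.
#' @export
estimatePeakVariances <- function(replicateGroups, matchTol = 0.5,
                                  floorMass = 1e-4, floorIntensity = 1e-3) {
  ssM <- 0; ssI <- 0; df <- 0
  for (group in replicateGroups) {
    if (length(group) < 2) next
    group <- lapply(group, normalizeIntensities)
    ref <- peakMatrix(group[[1]])
    clM <- as.list(ref[, 1]); clI <- as.list(ref[, 2])
    for (s in group[-1]) {
      p <- peakMatrix(s)
      for (k in seq_len(nrow(p))) {
        d <- abs(ref[, 1] - p[k, 1])
        j <- which.min(d)
        if (d[j] <= matchTol) {
          clM[[j]] <- c(clM[[j]], p[k, 1])
          clI[[j]] <- c(clI[[j]], p[k, 2])
        }
      }
    }
    for (j in seq_along(clM)) {
      nj <- length(clM[[j]])
      if (nj >= 2) {
        ssM <- ssM + sum((clM[[j]] - mean(clM[[j]]))^2)
        ssI <- ssI + sum((clI[[j]] - mean(clI[[j]]))^2)
        df <- df + (nj - 1)
      }
    }
  }
  if (df == 0)
    stop("no matchable replicate peaks; fall back to the default kernel ",
         "parameters (sigmaMass = 0.01 Da, sigmaIntensity = 0.05)")
  c(sigmaMass = max(sqrt(ssM / df), floorMass),
    sigmaIntensity = max(sqrt(ssI / df), floorIntensity))
}
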