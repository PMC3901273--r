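#' @include AllClasses.R
NULL

#' Accessors for MassSpectrum objects
#'
#' @param object,x a [MassSpectrum-class].
#' @param ... ignored.
#' @return `peakMatrix` returns the two-column peak matrix; `peakMasses` and
#'   `peakIntensities` its columns; `nPeaks` the peak count; the remaining
#'   accessors the corresponding metadata scalar.
#' @name MassSpectrum-accessors
NULL

#' @rdname MassSpectrum-accessors
#' @export
setGeneric("peakMatrix", function(object) standardGeneric("peakMatrix"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("peakMasses", function(object) standardGeneric("peakMasses"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("peakIntensities", function(object) standardGeneric("peakIntensities"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("msLevel", function(object) standardGeneric("msLevel"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("ionMode", function(object) standardGeneric("ionMode"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("instrumentTag", function(object) standardGeneric("instrumentTag"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))
#' @rdname MassSpectrum-accessors
#' @export
setGeneric("spectrumMetadata", function(object) standardGeneric("spectrumMetadata"))

#' @rdname MassSpectrum-accessors
#' @export
setMethod("peakMatrix", "MassSpectrum", function(object) object@peaks)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("peakMasses", "MassSpectrum", function(object) unname(object@peaks[, 1]))
#' @rdname MassSpectrum-accessors
#' @export
setMethod("peakIntensities", "MassSpectrum", function(object) unname(object@peaks[, 2]))
#' @rdname MassSpectrum-accessors
#' @export
setMethod("nPeaks", "MassSpectrum", function(object) nrow(object@peaks))
#' @rdname MassSpectrum-accessors
#' @export
setMethod("precursorMz", "MassSpectrum", function(object) object@precursorMz)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("msLevel", "MassSpectrum", function(object) object@msLevel)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("ionMode", "MassSpectrum", function(object) object@ionMode)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("instrumentTag", "MassSpectrum", function(object) object@instrument)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("moleculeId", "MassSpectrum", function(object) object@moleculeId)
#' @rdname MassSpectrum-accessors
#' @export
setMethod("spectrumMetadata", "MassSpectrum", function(object) object@metadata)

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum (MS%d, %s): %d peaks\n", object@msLevel,
              ifelse(is.na(object@ionMode), "mode ?", object@ionMode),
              nrow(object@peaks)))
  if (!is.na(object@precursorMz))
    cat(sprintf("  precursor m/z: %.6f\n", object@precursorMz))
  if (!is.na(object@instrument))
    cat("  instrument:", object@instrument, "\n")
  if (!is.na(object@moleculeId))
    cat("  molecule:", object@moleculeId, "\n")
  if (nrow(object@peaks)) {
    rng <- range(object@peaks[, 1])
    cat(sprintf("  mass range: %.4f - %.4f Da\n", rng[1], rng[2]))
  }
  invisible(object)
})

#' Accessors for KernelParams and GramMatrix
#'
#' @param object a [KernelParams-class] or [GramMatrix-class].
#' @name kernel-accessors
NULL

#' @rdname kernel-accessors
#' @export
setGeneric("sigmaMass", function(object) standardGeneric("sigmaMass"))
#' @rdname kernel-accessors
#' @export
setGeneric("sigmaIntensity", function(object) standardGeneric("sigmaIntensity"))
#' @rdname kernel-accessors
#' @export
setGeneric("kernelVariants", function(object) standardGeneric("kernelVariants"))
#' @rdname kernel-accessors
#' @export
setGeneric("gramValues", function(object) standardGeneric("gramValues"))
#' @rdname kernel-accessors
#' @export
setGeneric("kernelParams", function(object) standardGeneric("kernelParams"))

#' @rdname kernel-accessors
#' @export
setMethod("sigmaMass", "KernelParams", function(object) object@sigmaMass)
#' @rdname kernel-accessors
#' @export
setMethod("sigmaIntensity", "KernelParams", function(object) object@sigmaIntensity)
#' @rdname kernel-accessors
#' @export
setMethod("kernelVariants", "KernelParams", function(object) object@variants)
#' @rdname kernel-accessors
#' @export
setMethod("gramValues", "GramMatrix", function(object) {
  v <- object@values
  dimnames(v) <- list(object@rowIds, object@colIds)
  v
})
#' @rdname kernel-accessors
#' @export
setMethod("kernelParams", "GramMatrix", function(object) object@params)
#' @rdname kernel-accessors
#' @export
setMethod("kernelParams", "FingerprintModel", function(object) object@kernelParams)

setMethod("show", "KernelParams", function(object) {
  cat(sprintf("KernelParams: sigma_m = %g Da, sigma_i = %g, variants = {%s}, %s\n",
              object@sigmaMass, object@sigmaIntensity,
              paste(object@variants, collapse = ", "),
              if (object@normalize) "cosine-normalized" else "raw"))
  invisible(object)
})

setMethod("show", "GramMatrix", function(object) {
  cat(sprintf("GramMatrix: %d x %d\n", nrow(object@values), ncol(object@values)))
  show(object@params)
  invisible(object)
})

#' Accessors for CandidateSet objects
#'
#' @param object,x a [CandidateSet-class].
#' @param i index for subsetting.
#' @param j,drop,... ignored.
#' @name CandidateSet-accessors
NULL

#' @rdname CandidateSet-accessors
#' @export
setGeneric("candidateIds", function(object) standardGeneric("candidateIds"))
#' @rdname CandidateSet-accessors
#' @export
setGeneric("exactMasses", function(object) standardGeneric("exactMasses"))
#' @rdname CandidateSet-accessors
#' @export
setGeneric("formulas", function(object) standardGeneric("formulas"))
#' @rdname CandidateSet-accessors
#' @export
setGeneric("fingerprints", function(object) standardGeneric("fingerprints"))

#' @rdname CandidateSet-accessors
#' @export
setMethod("candidateIds", "CandidateSet", function(object) object@ids)
#' @rdname CandidateSet-accessors
#' @export
setMethod("exactMasses", "CandidateSet", function(object) object@exactMass)
#' @rdname CandidateSet-accessors
#' @export
setMethod("formulas", "CandidateSet", function(object) object@formula)
#' @rdname CandidateSet-accessors
#' @export
setMethod("fingerprints", "CandidateSet", function(object) {
  fp <- object@fingerprints
  rownames(fp) <- object@ids
  fp
})

#' @rdname CandidateSet-accessors
#' @export
setMethod("length", "CandidateSet", function(x) length(x@ids))

#' @rdname CandidateSet-accessors
#' @export
setMethod("[", "CandidateSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CandidateSet",
      ids = x@ids[i],
      exactMass = x@exactMass[i],
      formula = x@formula[i],
      fingerprints = x@fingerprints[i, , drop = FALSE])
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d molecules, %d fingerprint keys\n",
              length(object@ids), ncol(object@fingerprints)))
  if (length(object@ids)) {
    rng <- range(object@exactMass)
    cat(sprintf("  mass range: %.4f - %.4f Da\n", rng[1], rng[2]))
  }
  invisible(object)
})

#' Accessors for FingerprintModel objects
#'
#' @param object a [FingerprintModel-class].
#' @name FingerprintModel-accessors
NULL

#' @rdname FingerprintModel-accessors
#' @export
setGeneric("effectiveMask", function(object) standardGeneric("effectiveMask"))
#' @rdname FingerprintModel-accessors
#' @export
setGeneric("reliabilityScores", function(object) standardGeneric("reliabilityScores"))
#' @rdname FingerprintModel-accessors
#' @export
setGeneric("schemaHash", function(object) standardGeneric("schemaHash"))
#' @rdname FingerprintModel-accessors
#' @export
setGeneric("keyNames", function(object) standardGeneric("keyNames"))

#' @rdname FingerprintModel-accessors
#' @export
setMethod("effectiveMask", "FingerprintModel", function(object) {
  stats::setNames(object@mask, object@keyNames)
})
#' @rdname FingerprintModel-accessors
#' @export
setMethod("reliabilityScores", "FingerprintModel", function(object) {
  stats::setNames(object@reliability, object@keyNames[object@mask])
})
#' @rdname FingerprintModel-accessors
#' @export
setMethod("schemaHash", "FingerprintModel", function(object) object@schemaHash)
#' @rdname FingerprintModel-accessors
#' @export
setMethod("keyNames", "FingerprintModel", function(object) object@keyNames)

setMethod("show", "FingerprintModel", function(object) {
  cat(sprintf("FingerprintModel (v%s): %d effective / %d total bits\n",
              object@version, sum(object@mask), length(object@mask)))
  cat(sprintf("  %d training spectra of %d molecules\n",
              length(object@trainingSpectra), length(unique(object@moleculeOf))))
  if (length(object@reliability))
    cat(sprintf("  reliability: mean %.3f, range %.3f - %.3f\n",
                mean(object@reliability), min(object@reliability),
                max(object@reliability)))
  show(object@kernelParams)
  invisible(object)
})

#' Normalize spectrum intensities to sum to one
#'
#' Scales the intensity column so that intensities sum to exactly one,
#' leaving masses untouched. The operation is idempotent. Spectra must
#' carry at least one peak with positive intensity.
#'
#' @param object a [MassSpectrum-class].
#' @return A [MassSpectrum-class] with intensities summing to 1.
#' @examples
#' s <- MassSpectrum(mass = c(100, 200), intensity = c(1, 3))
#' peakIntensities(normalizeIntensities(s))  # 0.25 0.75
#' @export
setGeneric("normalizeIntensities", function(object) standardGeneric("normalizeIntensities"))

#' Predict a fingerprint vector for a query spectrum
#'
#' Evaluates each per-bit kernel SVM expansion against the query spectrum:
#' bit j is the sign of `sum_i alphaY_ij K(chi_i, chi_query) + bias_j`, with
#' a decision value of exactly zero mapped to +1. Constant bits return their
#' stored class without any kernel evaluation.
#'
#' @param object a trained [FingerprintModel-class].
#' @param query a [MassSpectrum-class] (normalized internally).
#' @return Named integer vector over the model's effective bits, values
#'   ±1, with attribute `schemaHash`.
#' @export
setGeneric("predictFingerprints", function(object, query) standardGeneric("predictFingerprints"))
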