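#' @import methods
NULL

#' MassSpectrum: a peak list with acquisition metadata
#'
#' Container for a single mass spectrum: an ordered peak matrix plus the
#' precursor m/z, MS level, ionization mode, instrument tag and an optional
#' link to the measured molecule. Peaks are stored sorted by ascending mass
#' and duplicate masses are merged (intensities summed) at construction
#' time, so every valid object has strictly increasing peak masses.
#'
#' @slot peaks numeric matrix with columns `mass` (Da) and `intensity`
#'   (relative abundance).
#' @slot precursorMz numeric(1); precursor m/z in Da, `NA` if unknown.
#' @slot msLevel integer(1); 1 for MS1, 2 for MS/MS.
#' @slot ionMode character(1); `"positive"`, `"negative"` or `NA`.
#' @slot instrument character(1); free-form device/ionization/fragmentation
#'   tag such as `"LC-ESI-ITFT-CID"`.
#' @slot moleculeId character(1); identifier of the measured molecule, `NA`
#'   when unknown (query spectra).
#' @slot metadata list of unparsed/auxiliary header fields.
#' @seealso [MassSpectrum()], [parseMassBankRecord()], [parsePeakList()]
#' @exportClass MassSpectrum
setClass("MassSpectrum",
  representation(
    peaks = "matrix",
    precursorMz = "numeric",
    msLevel = "integer",
    ionMode = "character",
    instrument = "character",
    moleculeId = "character",
    metadata = "list"
  ),
  prototype(
    peaks = matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("mass", "intensity"))),
    precursorMz = NA_real_,
    msLevel = 2L,
    ionMode = NA_character_,
    instrument = NA_character_,
    moleculeId = NA_character_,
    metadata = list()
  )
)

setValidity("MassSpectrum", function(object) {
  p <- object@peaks
  msgs <- character(0)
  if (!is.numeric(p) || ncol(p) != 2)
    return("peaks must be a numeric matrix with two columns (mass, intensity)")
  if (nrow(p) > 0) {
    if (any(!is.finite(p))) msgs <- c(msgs, "peaks must be finite")
    if (any(p[, 1] <= 0)) msgs <- c(msgs, "peak masses must be positive")
    if (any(p[, 2] < 0)) msgs <- c(msgs, "peak intensities must be non-negative")
    if (is.unsorted(p[, 1], strictly = TRUE))
      msgs <- c(msgs, "peak masses must be strictly increasing (merge duplicates first)")
  }
  if (length(object@precursorMz) != 1) msgs <- c(msgs, "precursorMz must have length 1")
  if (!object@msLevel %in% c(1L, 2L)) msgs <- c(msgs, "msLevel must be 1 or 2")
  if (!is.na(object@ionMode) &&
      !object@ionMode %in% c("positive", "negative"))
    msgs <- c(msgs, "ionMode must be 'positive', 'negative' or NA")
  if (length(msgs)) msgs else TRUE
})

#' KernelParams: parameters of the probability product kernel
#'
#' Bundles the shared Gaussian peak-model standard deviations, the set of
#' kernel variants to evaluate, and whether variant values are
#' cosine-normalized before being summed.
#'
#' @slot sigmaMass numeric(1); mass standard deviation in Da (> 0).
#' @slot sigmaIntensity numeric(1); intensity standard deviation in relative
#'   units after sum-to-one normalization (> 0).
#' @slot variants character; non-empty subset of `c("peaks","mloss","diff")`.
#' @slot normalize logical(1); cosine-normalize each variant before summing.
#' @seealso [KernelParams()]
#' @exportClass KernelParams
setClass("KernelParams",
  representation(
    sigmaMass = "numeric",
    sigmaIntensity = "numeric",
    variants = "character",
    normalize = "logical"
  )
)

setValidity("KernelParams", function(object) {
  msgs <- character(0)
  if (length(object@sigmaMass) != 1 || !is.finite(object@sigmaMass) ||
      object@sigmaMass <= 0)
    msgs <- c(msgs, "sigmaMass must be a single positive number")
  if (length(object@sigmaIntensity) != 1 || !is.finite(object@sigmaIntensity) ||
      object@sigmaIntensity <= 0)
    msgs <- c(msgs, "sigmaIntensity must be a single positive number")
  if (length(object@variants) == 0 ||
      !all(object@variants %in% c("peaks", "mloss", "diff")))
    msgs <- c(msgs, "variants must be a non-empty subset of peaks/mloss/diff")
  if (anyDuplicated(object@variants))
    msgs <- c(msgs, "variants must not repeat")
  if (length(object@normalize) != 1 || is.na(object@normalize))
    msgs <- c(msgs, "normalize must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' GramMatrix: a batch of kernel evaluations
#'
#' Dense matrix of (combined, optionally normalized) kernel values between
#' two lists of spectra, together with their identifiers and the kernel
#' parameters used. Square matrices (rows == cols) are symmetric and
#' positive semidefinite up to numerical tolerance.
#'
#' @slot values numeric matrix.
#' @slot rowIds,colIds character identifiers matching the matrix dimensions.
#' @slot params the [KernelParams-class] used.
#' @seealso [gramMatrix()]
#' @exportClass GramMatrix
setClass("GramMatrix",
  representation(
    values = "matrix",
    rowIds = "character",
    colIds = "character",
    params = "KernelParams"
  )
)

setValidity("GramMatrix", function(object) {
  msgs <- character(0)
  if (nrow(object@values) != length(object@rowIds))
    msgs <- c(msgs, "rowIds length must match nrow(values)")
  if (ncol(object@values) != length(object@colIds))
    msgs <- c(msgs, "colIds length must match ncol(values)")
  if (anyDuplicated(object@rowIds)) msgs <- c(msgs, "rowIds must be unique")
  if (anyDuplicated(object@colIds)) msgs <- c(msgs, "colIds must be unique")
  if (length(msgs)) msgs else TRUE
})

#' CandidateSet: a molecular database slice
#'
#' Aligned storage for database molecules: identifier, neutral exact mass,
#' elemental formula and a ±1 fingerprint matrix (one row per molecule, one
#' column per fingerprint key). Subsetting with `[` keeps all four in step.
#'
#' @slot ids character molecule identifiers (unique).
#' @slot exactMass numeric neutral monoisotopic masses in Da.
#' @slot formula character elemental formulas (Hill notation; may be `NA`).
#' @slot fingerprints integer matrix over {+1, -1}; `colnames` are the
#'   fingerprint key names.
#' @seealso [CandidateSet()], [readCandidateTable()], [computeFingerprints()]
#' @exportClass CandidateSet
setClass("CandidateSet",
  representation(
    ids = "character",
    exactMass = "numeric",
    formula = "character",
    fingerprints = "matrix"
  )
)

setValidity("CandidateSet", function(object) {
  n <- length(object@ids)
  msgs <- character(0)
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "molecule ids must be unique")
  if (length(object@exactMass) != n) msgs <- c(msgs, "exactMass length mismatch")
  if (length(object@formula) != n) msgs <- c(msgs, "formula length mismatch")
  if (nrow(object@fingerprints) != n) msgs <- c(msgs, "fingerprint row mismatch")
  if (n > 0) {
    if (any(!is.finite(object@exactMass)) || any(object@exactMass <= 0))
      msgs <- c(msgs, "exact masses must be positive")
    if (nrow(object@fingerprints) > 0 &&
        !all(object@fingerprints %in% c(-1L, 1L)))
      msgs <- c(msgs, "fingerprint bits must be +1 or -1")
  }
  if (is.null(colnames(object@fingerprints)))
    msgs <- c(msgs, "fingerprint matrix must carry key names as colnames")
  if (length(msgs)) msgs else TRUE
})

#' FingerprintModel: trained per-bit SVM ensemble
#'
#' The result of [trainFingerprintModel()]: one kernel-SVM dual solution per
#' effective fingerprint bit, the effective-bit mask over the full key
#' schema, per-bit cross-validated reliability scores, the kernel
#' parameters, and the training spectra (needed at prediction time to
#' evaluate the kernel expansion against a query).
#'
#' @slot version character(1) model-format version.
#' @slot kernelParams the [KernelParams-class] the model was trained with.
#' @slot keyNames character; full fingerprint key schema (length m_total).
#' @slot mask logical over keyNames; TRUE for effective (trained) bits.
#' @slot reliability numeric in \[0,1\] over effective bits: cross-validated
#'   prediction accuracy w_j, used as Poisson-binomial weights.
#' @slot bitModels list over effective bits; each element a list with
#'   fields `constant`, `value` (for constant bits), `alphaY`, `support`,
#'   `bias`, `C` (for SVM bits).
#' @slot trainingSpectra list of [MassSpectrum-class] (normalized).
#' @slot trainingIds character spectrum identifiers.
#' @slot moleculeOf character; molecule id per training spectrum.
#' @slot selfSim numeric matrix (n training spectra x variants) of raw
#'   self-similarities, used for kernel normalization at prediction time.
#' @slot schemaHash character(1); hash of keyNames guarding model/database
#'   agreement.
#' @slot seed integer(1) training seed.
#' @exportClass FingerprintModel
setClass("FingerprintModel",
  representation(
    version = "character",
    kernelParams = "KernelParams",
    keyNames = "character",
    mask = "logical",
    reliability = "numeric",
    bitModels = "list",
    trainingSpectra = "list",
    trainingIds = "character",
    moleculeOf = "character",
    selfSim = "matrix",
    schemaHash = "character",
    seed = "integer"
  )
)

setValidity("FingerprintModel", function(object) {
  msgs <- character(0)
  m <- sum(object@mask)
  if (length(object@mask) != length(object@keyNames))
    msgs <- c(msgs, "mask length must match keyNames")
  if (length(object@reliability) != m)
    msgs <- c(msgs, "one reliability score per effective bit required")
  if (length(object@bitModels) != m)
    msgs <- c(msgs, "one bit model per effective bit required")
  if (length(object@trainingSpectra) != length(object@trainingIds))
    msgs <- c(msgs, "trainingIds must match trainingSpectra")
  if (length(object@moleculeOf) != length(object@trainingSpectra))
    msgs <- c(msgs, "moleculeOf must match trainingSpectra")
  if (length(object@reliability) &&
      (any(object@reliability < 0) || any(object@reliability > 1)))
    msgs <- c(msgs, "reliability scores must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})
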