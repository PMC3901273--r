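#' Physical and chemical constants
#'
#' All mass constants used by the package live in this one table so that
#' precursor estimation, mass-loss transforms and isotope simulation cannot
#' drift apart.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{protonMass}{Mass of the proton in Da, used for the
#'     \code{[M+H]+} / \code{[M-H]-} adduct shifts.}
#' }
#' @export
fmsConstants <- list(
  protonMass = 1.007276466
)

## Stable-isotope table: monoisotopic masses (Da) and natural abundances.
## Carbon abundances follow the classical 98.890/1.110 values; other
## elements use standard IUPAC terrestrial values. Abundances per element
## sum to 1 and masses are strictly increasing.
.isotopeData <- list(
  C  = list(mass = c(12.000000000, 13.003354838), abundance = c(0.98890, 0.01110)),
  H  = list(mass = c(1.007825032, 2.014101778),   abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.003074005, 15.000108898), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.994914622, 16.999131757, 17.999159613),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.973761998, abundance = 1.0),
  S  = list(mass = c(31.972071174, 32.971458910, 33.967866800, 35.967080710),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.989769282, abundance = 1.0),
  Cl = list(mass = c(34.968852682, 36.965902602), abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.963706487, 39.963998166, 40.961825258),
            abundance = c(0.932581, 0.000117, 0.067302))
)

#' Default stable-isotope table
#'
#' Returns the built-in table of stable isotopes (CHNOPS plus Na, Cl, K)
#' used by [elementPattern()] and [moleculePattern()]. Each entry holds the
#' isotope masses in Da (ascending) and their natural abundances (summing
#' to one). A user table of the same shape, e.g. read from a YAML file with
#' [readIsotopeTable()], can be passed to the pattern functions instead.
#'
#' @return Named list; one element per chemical element, each a list with
#'   numeric vectors `mass` and `abundance`.
#' @examples
#' isotopeTable()$C
#' @export
isotopeTable <- function() .isotopeData

#' Read an isotope table from a YAML file
#'
#' The file must map element symbols to `mass` and `abundance` sequences,
#' mirroring the shape of [isotopeTable()].
#'
#' @param path Path to a YAML file.
#' @return Isotope table list, validated.
#' @export
readIsotopeTable <- function(path) {
  tab <- yaml::read_yaml(path)
  for (el in names(tab)) {
    entry <- tab[[el]]
    if (is.null(entry$mass) || is.null(entry$abundance))
      stop("isotope table entry for '", el, "' needs 'mass' and 'abundance'")
    tab[[el]]$mass <- as.numeric(entry$mass)
    tab[[el]]$abundance <- as.numeric(entry$abundance)
    .checkIsotopeEntry(el, tab[[el]])
  }
  tab
}

.checkIsotopeEntry <- function(symbol, entry) {
  if (length(entry$mass) != length(entry$abundance))
    stop("isotope table entry for '", symbol, "': mass/abundance length mismatch")
  if (abs(sum(entry$abundance) - 1) > 1e-9)
    stop("isotope table entry for '", symbol, "': abundances must sum to 1")
  if (is.unsorted(entry$mass, strictly = TRUE))
    stop("isotope table entry for '", symbol, "': masses must be strictly increasing")
  invisible(TRUE)
}

## Fingerprint family sizes (OpenBabel): FP3 55, FP4 307, MACCS 166 = 528.
.fpFamilies <- c(FP3 = 55L, FP4 = 307L, MACCS = 166L)

#' Names of the 528 fingerprint keys
#'
#' The fixed bit order of the concatenated OpenBabel fingerprint families
#' (FP3, FP4, MACCS). The order is frozen; a hash of these names travels
#' with trained models and candidate databases so the two cannot silently
#' disagree.
#'
#' @return Character vector of length 528.
#' @export
fingerprintKeyNames <- function() {
  unlist(lapply(names(.fpFamilies), function(fam) {
    sprintf("%s_%03d", fam, seq_len(.fpFamilies[[fam]]))
  }), use.names = FALSE)
}
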