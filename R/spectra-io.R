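#' @include AllGenerics.R
NULL

#' Construct a MassSpectrum
#'
#' Builds a [MassSpectrum-class] from mass/intensity vectors. Peaks are
#' sorted by ascending mass and duplicate masses are merged by summing
#' their intensities, so the resulting object always has strictly
#' increasing peak masses.
#'
#' @param mass numeric; peak masses in Da (> 0).
#' @param intensity numeric; peak intensities (>= 0), same length as `mass`.
#' @param precursorMz numeric(1); precursor m/z in Da, `NA` if unknown.
#' @param msLevel 1 or 2.
#' @param ionMode `"positive"`, `"negative"` or `NA`.
#' @param instrument free-form instrument tag.
#' @param moleculeId identifier of the measured molecule, or `NA`.
#' @param metadata list of auxiliary fields.
#' @return A [MassSpectrum-class].
#' @examples
#' MassSpectrum(c(100.05, 150.1), c(0.4, 0.6), precursorMz = 181.07)
#' @export
MassSpectrum <- function(mass, intensity, precursorMz = NA_real_,
                         msLevel = 2L, ionMode = NA_character_,
                         instrument = NA_character_,
                         moleculeId = NA_character_, metadata = list()) {
  if (length(mass) != length(intensity))
    stop("mass and intensity must have equal length")
  if (length(mass)) {
    o <- order(mass)
    mass <- mass[o]; intensity <- intensity[o]
    grp <- cumsum(c(TRUE, diff(mass) > 0))
    if (max(grp) < length(mass)) {
      intensity <- as.numeric(tapply(intensity, grp, sum))
      mass <- mass[!duplicated(grp)]
    }
  }
  new("MassSpectrum",
      peaks = matrix(c(mass, intensity), ncol = 2,
                     dimnames = list(NULL, c("mass", "intensity"))),
      precursorMz = as.numeric(precursorMz)[1],
      msLevel = as.integer(msLevel),
      ionMode = as.character(ionMode)[1],
      instrument = as.character(instrument)[1],
      moleculeId = as.character(moleculeId)[1],
      metadata = metadata)
}

#' @rdname normalizeIntensities
#' @export
setMethod("normalizeIntensities", "MassSpectrum", function(object) {
  ints <- object@peaks[, 2]
  tot <- sum(ints)
  if (nrow(object@peaks) == 0 || tot <= 0)
    stop("cannot normalize a spectrum without positive intensities")
  object@peaks[, 2] <- ints / tot
  object
})

## --- MassBank record I/O -------------------------------------------------

#' Parse one MassBank record
#'
#' Reads a MassBank-formatted record (ACCESSION header, metadata fields,
#' PK$PEAK block) into a [MassSpectrum-class]. Recognized fields populate
#' the spectrum slots; unrecognized header lines are preserved verbatim in
#' `spectrumMetadata()`. The record must contain an `ACCESSION` line and a
#' `PK$PEAK:` block; everything else is optional.
#'
#' Recognized fields: `MS$FOCUSED_ION: PRECURSOR_M/Z` (precursor),
#' `AC$MASS_SPECTROMETRY: MS_TYPE` (MS level), `AC$MASS_SPECTROMETRY:
#' ION_MODE`, `AC$INSTRUMENT_TYPE`, `CH$NAME` (molecule identifier).
#'
#' @param text character; the record as a single string or vector of lines.
#' @return A [MassSpectrum-class].
#' @seealso [writeMassBankRecord()], [readMassBankFile()]
#' @export
parseMassBankRecord <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  accIdx <- grep("^ACCESSION:", lines)
  if (!length(accIdx))
    stop("MassBank record has no ACCESSION line")
  accession <- trimws(sub("^ACCESSION:", "", lines[accIdx[1]]))
  pkIdx <- grep("^PK\\$PEAK:", lines)
  if (!length(pkIdx))
    stop("MassBank record '", accession, "' has no PK$PEAK block")

  header <- lines[seq_len(pkIdx[1])]
  field <- function(pattern) {
    hit <- grep(pattern, header, value = TRUE)
    if (length(hit)) trimws(sub(pattern, "", hit[1])) else NA_character_
  }
  precursor <- field("^MS\\$FOCUSED_ION: PRECURSOR_M/Z")
  precursor <- if (is.na(precursor)) NA_real_ else suppressWarnings(as.numeric(precursor))
  msType <- field("^AC\\$MASS_SPECTROMETRY: MS_TYPE")
  msLevel <- if (!is.na(msType) && toupper(msType) == "MS") 1L else 2L
  modeRaw <- field("^AC\\$MASS_SPECTROMETRY: ION_MODE")
  ionMode <- if (is.na(modeRaw)) NA_character_
             else if (toupper(modeRaw) %in% c("POSITIVE", "P")) "positive"
             else if (toupper(modeRaw) %in% c("NEGATIVE", "N")) "negative"
             else NA_character_
  instrument <- field("^AC\\$INSTRUMENT_TYPE:")
  molecule <- field("^CH\\$NAME:")

  known <- "^(ACCESSION:|MS\\$FOCUSED_ION: PRECURSOR_M/Z|AC\\$MASS_SPECTROMETRY: (MS_TYPE|ION_MODE)|AC\\$INSTRUMENT_TYPE:|CH\\$NAME:|PK\\$PEAK:|PK\\$NUM_PEAK:)"
  extra <- header[!grepl(known, header) & nzchar(trimws(header))]

  peakLines <- lines[seq(pkIdx[1] + 1, length.out = max(0, length(lines) - pkIdx[1]))]
  peakLines <- peakLines[!grepl("^//\\s*$", peakLines)]
  peakLines <- peakLines[nzchar(trimws(peakLines))]
  if (!length(peakLines))
    stop("MassBank record '", accession, "' has an empty PK$PEAK block")
  mass <- numeric(length(peakLines)); intensity <- numeric(length(peakLines))
  for (k in seq_along(peakLines)) {
    tok <- strsplit(trimws(peakLines[k]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("malformed peak line ", pkIdx[1] + k, " in record '", accession,
           "': '", peakLines[k], "'")
    mass[k] <- vals[1]
    intensity[k] <- vals[2]
  }
  MassSpectrum(mass, intensity, precursorMz = precursor, msLevel = msLevel,
               ionMode = ionMode, instrument = instrument,
               moleculeId = molecule,
               metadata = list(accession = accession, extraFields = extra))
}

#' Serialize a MassSpectrum as a MassBank record
#'
#' Writes the fields that [parseMassBankRecord()] recognizes, so
#' parse-write-parse round-trips reproduce the spectrum field-wise.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param accession record accession string; defaults to the stored one.
#' @return Character scalar holding the record text (terminated by `//`).
#' @export
writeMassBankRecord <- function(spectrum, accession = NULL) {
  if (is.null(accession))
    accession <- spectrum@metadata$accession %||% "FMS000000"
  lines <- c(paste("ACCESSION:", accession))
  if (!is.na(spectrum@moleculeId))
    lines <- c(lines, paste("CH$NAME:", spectrum@moleculeId))
  if (!is.na(spectrum@instrument))
    lines <- c(lines, paste("AC$INSTRUMENT_TYPE:", spectrum@instrument))
  lines <- c(lines, paste("AC$MASS_SPECTROMETRY: MS_TYPE",
                          if (spectrum@msLevel == 1L) "MS" else "MS2"))
  if (!is.na(spectrum@ionMode))
    lines <- c(lines, paste("AC$MASS_SPECTROMETRY: ION_MODE",
                            toupper(spectrum@ionMode)))
  if (!is.na(spectrum@precursorMz))
    lines <- c(lines, sprintf("MS$FOCUSED_ION: PRECURSOR_M/Z %.10g",
                              spectrum@precursorMz))
  extra <- spectrum@metadata$extraFields
  if (length(extra)) lines <- c(lines, extra)
  p <- spectrum@peaks
  lines <- c(lines,
             sprintf("PK$NUM_PEAK: %d", nrow(p)),
             "PK$PEAK: m/z int. rel.int.",
             sprintf("  %.10g %.10g %.10g", p[, 1], p[, 2], p[, 2]),
             "//")
  paste(lines, collapse = "\n")
}

#' Read a multi-record MassBank file
#'
#' Records are separated by `//` lines (the MassBank convention).
#'
#' @param path file path.
#' @return Named list of [MassSpectrum-class]; names are accessions.
#' @export
readMassBankFile <- function(path) {
  lines <- readLines(path)
  idx <- cumsum(c(0, head(grepl("^//\\s*$", lines), -1)))
  chunks <- split(lines, idx)
  chunks <- Filter(function(ch) any(grepl("^ACCESSION:", ch)), chunks)
  out <- lapply(chunks, parseMassBankRecord)
  names(out) <- vapply(out, function(s) s@metadata$accession, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- Plain peak lists ----------------------------------------------------

#' Parse a plain two-column peak list
#'
#' Accepts whitespace- or comma-separated numeric text with one
#' `mass intensity` pair per line (blank lines and `#` comments ignored).
#' This is the query format of the web-form style interface.
#'
#' @param text character; the peak list as one string or vector of lines.
#' @param precursorMz optional precursor m/z to attach.
#' @param ionMode optional ionization mode to attach.
#' @param msLevel MS level of the list (default 2).
#' @return A [MassSpectrum-class] (duplicate masses merged, sorted).
#' @examples
#' parsePeakList("100.0 1.0\n200.0 3.0")
#' @export
parsePeakList <- function(text, precursorMz = NA_real_,
                          ionMode = NA_character_, msLevel = 2L) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty peak list")
  mass <- numeric(length(idx)); intensity <- numeric(length(idx))
  for (k in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[k]]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("non-numeric peak entry on line ", idx[k], ": '", lines[idx[k]], "'")
    mass[k] <- vals[1]; intensity[k] <- vals[2]
  }
  MassSpectrum(mass, intensity, precursorMz = precursorMz,
               msLevel = msLevel, ionMode = ionMode)
}

## --- Exact-mass estimation ----------------------------------------------

#' Estimate the neutral exact mass from an MS1 spectrum
#'
#' Takes the most abundant MS1 peak as the precursor (ties broken toward
#' the lower mass, which favours the monoisotopic peak) and converts it to
#' a neutral mass under the protonation adduct: `precursor - m_p` in
#' positive mode (`[M+H]+`), `precursor + m_p` in negative mode
#' (`[M-H]-`), with `m_p = 1.007276466` Da from [fmsConstants].
#'
#' Other adducts (e.g. `[M+Na]+`, `[M+2H]2+`) occur in practice; this
#' estimator deliberately assumes protonation and records the assumption in
#' the result so callers can override the mass when they know better.
#'
#' @param ms1 a [MassSpectrum-class] with at least one peak.
#' @param mode `"positive"` or `"negative"`; defaults to the spectrum's own
#'   ionization mode.
#' @return List with `neutralMass`, `precursorMz` and `adduct`.
#' @examples
#' s <- MassSpectrum(c(181.0495, 182.0529), c(100, 10), msLevel = 1)
#' estimateExactMass(s, "positive")$neutralMass  # 180.042224
#' @export
estimateExactMass <- function(ms1, mode = ionMode(ms1)) {
  if (nPeaks(ms1) == 0) stop("cannot estimate the exact mass of an empty spectrum")
  if (is.na(mode) || !mode %in% c("positive", "negative"))
    stop("mode must be 'positive' or 'negative'")
  p <- peakMatrix(ms1)
  best <- which(p[, 2] == max(p[, 2]))
  prec <- min(p[best, 1])  # tie: lowest mass (monoisotopic precedes isotopes)
  if (mode == "positive") {
    list(neutralMass = prec - fmsConstants$protonMass, precursorMz = prec,
         adduct = "[M+H]+")
  } else {
    list(neutralMass = prec + fmsConstants$protonMass, precursorMz = prec,
         adduct = "[M-H]-")
  }
}
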