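#' @include AllGenerics.R kernels.R
NULL

## All compositions (k_1..k_r >= 0, sum = l): one row per composition.
.compositions <- function(l, r) {
  if (r == 1) return(matrix(l, 1, 1))
  out <- NULL
  for (k1 in l:0) {
    rest <- .compositions(l - k1, r - 1)
    out <- rbind(out, cbind(k1, rest))
  }
  unname(out)
}

#' Isotope pattern of l atoms of one element
#'
#' Enumerates all isotopologues of `l` atoms of one element - the
#' multisets of size `l` over its `r` stable isotopes, of which there are
#' `choose(l + r - 1, r - 1)` - and assigns each the multinomial
#' probability of its isotope counts under the natural abundances. Entry
#' masses are the summed isotope masses.
#'
#' @param element element symbol (looked up in `table`) or a list with
#'   `mass` and `abundance` vectors.
#' @param count number of atoms `l` (>= 0); `l = 0` gives the empty
#'   product: a single entry of mass 0 and abundance 1.
#' @param table isotope table (default [isotopeTable()]).
#' @return List of class `IsotopePattern` with `mass` (ascending),
#'   `abundance` (sums to 1) and `formula`.
#' @examples
#' elementPattern("C", 1)$abundance  # 0.98890 0.01110
#' @export
elementPattern <- function(element, count, table = isotopeTable()) {
  if (count < 0) stop("atom count must be non-negative")
  if (is.character(element)) {
    symbol <- element
    if (is.null(table[[symbol]])) stop("unknown element symbol '", symbol, "'")
    element <- table[[symbol]]
  } else symbol <- "?"
  .checkIsotopeEntry(symbol, element)
  if (count == 0)
    return(.isotopePattern(0, 1, paste0(symbol, "0")))
  r <- length(element$mass)
  comp <- .compositions(count, r)
  mass <- drop(comp %*% element$mass)
  logAb <- lgamma(count + 1) - rowSums(lgamma(comp + 1)) +
    drop(comp %*% log(element$abundance))
  .isotopePattern(mass, exp(logAb),
                  paste0(symbol, if (count > 1) count else ""))
}

.isotopePattern <- function(mass, abundance, formula) {
  o <- order(mass)
  structure(list(mass = mass[o], abundance = abundance[o], formula = formula),
            class = "IsotopePattern")
}

#' @export
print.IsotopePattern <- function(x, ...) {
  cat(sprintf("IsotopePattern for %s: %d entries\n", x$formula, length(x$mass)))
  show <- utils::head(seq_along(x$mass), 8)
  for (i in show)
    cat(sprintf("  %12.6f Da  %.6g\n", x$mass[i], x$abundance[i]))
  if (length(x$mass) > 8) cat("  ...\n")
  invisible(x)
}

#' Parse a molecular formula in Hill notation
#'
#' @param formula e.g. `"C6H12O6"`; element symbols with optional counts.
#' @return Named integer vector of atom counts.
#' @export
parseFormula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("cannot parse formula '", formula, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  els <- sub("[0-9]+$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  vapply(split(cnt, factor(els, levels = unique(els))), sum, integer(1))
}

## Merge pattern entries closer than tol (abundance-weighted mean mass).
.mergePattern <- function(mass, abundance, tol) {
  if (tol <= 0 || length(mass) < 2) return(list(mass = mass, abundance = abundance))
  o <- order(mass); mass <- mass[o]; abundance <- abundance[o]
  grp <- cumsum(c(TRUE, diff(mass) > tol))
  list(mass = as.numeric(tapply(mass * abundance, grp, sum) /
                           tapply(abundance, grp, sum)),
       abundance = as.numeric(tapply(abundance, grp, sum)))
}

#' Theoretical isotope pattern of a molecular formula
#'
#' Convolves the per-element isotopologue patterns ([elementPattern()])
#' across the elements of the formula: masses add, abundances multiply.
#' Entries closer than `mergeTol` are merged (abundance-weighted mean
#' mass, summed abundance) and entries below `pruneBelow` are dropped,
#' after which abundances are renormalized to sum to one. With
#' `pruneBelow = 0` and a tiny tolerance the unpruned abundances sum to 1
#' up to floating-point error and the lightest entry is the monoisotopic
#' mass.
#'
#' @param formula Hill-notation formula string, e.g. `"C6H12O6"`.
#' @param table isotope table (default [isotopeTable()]).
#' @param pruneBelow abundance threshold in \[0, 1) (default 1e-5).
#' @param mergeTol merge tolerance in Da (default 1e-4, high-resolution
#'   regime).
#' @return An `IsotopePattern` (see [elementPattern()]).
#' @examples
#' head(moleculePattern("C6H12O6")$mass, 1)  # 180.0634
#' @export
moleculePattern <- function(formula, table = isotopeTable(),
                            pruneBelow = 1e-5, mergeTol = 1e-4) {
  if (pruneBelow < 0 || pruneBelow >= 1) stop("pruneBelow must be in [0, 1)")
  counts <- parseFormula(formula)
  mass <- 0; abundance <- 1
  ## intermediate pruning far below the final threshold keeps the
  ## convolution exact to well within the requested precision
  interPrune <- pruneBelow * 1e-3
  for (el in names(counts)) {
    ep <- elementPattern(el, counts[[el]], table)
    mass <- outer(mass, ep$mass, "+")
    abundance <- outer(abundance, ep$abundance, "*")
    mg <- .mergePattern(as.numeric(mass), as.numeric(abundance), mergeTol)
    keep <- mg$abundance >= interPrune
    mass <- mg$mass[keep]; abundance <- mg$abundance[keep]
  }
  keep <- abundance >= pruneBelow
  mass <- mass[keep]; abundance <- abundance[keep]
  abundance <- abundance / sum(abundance)
  .isotopePattern(mass, abundance, formula)
}

#' Convert an isotope pattern to an MS1 spectrum
#'
#' Shifts the isotopologue masses by the adduct for the given ionization
#' mode (`+m_p` for `[M+H]+`, `-m_p` for `[M-H]-`) and uses the
#' abundances, sum-normalized, as intensities.
#'
#' @param pattern an `IsotopePattern`.
#' @param mode `"positive"` or `"negative"`.
#' @return A [MassSpectrum-class] at MS level 1.
#' @export
patternToSpectrum <- function(pattern, mode = "positive") {
  if (!length(pattern$mass)) stop("empty isotope pattern")
  shift <- if (mode == "positive") fmsConstants$protonMass
           else if (mode == "negative") -fmsConstants$protonMass
           else stop("mode must be 'positive' or 'negative'")
  normalizeIntensities(MassSpectrum(pattern$mass + shift, pattern$abundance,
                                    msLevel = 1L, ionMode = mode,
                                    moleculeId = pattern$formula))
}

#' Match an observed MS1 spectrum against a theoretical isotope pattern
#'
#' Converts the pattern to an MS1 spectrum ([patternToSpectrum()]) and
#' evaluates the cosine-normalized probability product kernel (peaks
#' variant) against the observed spectrum: 1 for a perfect match,
#' approaching 0 when the envelopes do not overlap.
#'
#' @param observed an observed MS1 [MassSpectrum-class] (non-empty).
#' @param pattern an `IsotopePattern`.
#' @param mode ionization mode for the adduct shift; defaults to the
#'   observed spectrum's mode.
#' @param params [KernelParams-class]; only the sigmas are used (MS1
#'   matching always uses the peaks variant). The mass sigma may be set
#'   separately from the MS2 kernel if the MS1 accuracy differs.
#' @return numeric score in (0, 1\].
#' @export
isotopeMatchScore <- function(observed, pattern, mode = ionMode(observed),
                              params = KernelParams()) {
  if (nPeaks(observed) == 0) stop("observed MS1 spectrum is empty")
  if (is.na(mode)) stop("ionization mode required for the adduct shift")
  theo <- patternToSpectrum(pattern, mode)
  obs <- normalizeIntensities(observed)
  k12 <- kernelValue(obs, theo, "peaks", params)
  k11 <- kernelValue(obs, obs, "peaks", params)
  k22 <- kernelValue(theo, theo, "peaks", params)
  k12 / sqrt(k11 * k22)
}

#' Fuse fingerprint-based and isotope-based rankings
#'
#' Combines two ranked lists over the same candidate set:
#' \describe{
#'   \item{average}{re-sort by the mean of the two ranks;}
#'   \item{minrank}{re-sort by the smaller of the two ranks;}
#'   \item{rerank}{sort by the isotope score and break isotope-score ties
#'     (molecules sharing a formula share an isotope score) by the
#'     fingerprint score.}
#' }
#' Remaining ties are broken by ascending molecule identifier and final
#' ranks re-assigned 1..n.
#'
#' @param fpList ranking from [rankCandidates()] (fingerprint scores).
#' @param isoList ranking of the same candidates by isotope match score
#'   (`logScore` column holds the isotope score).
#' @param method `"average"`, `"minrank"` or `"rerank"`.
#' @return `data.frame` like [rankCandidates()] output, with columns
#'   `rank`, `moleculeId`, `fpRank`, `isoRank`, `fpScore`, `isoScore`.
#' @export
aggregateRanks <- function(fpList, isoList, method = c("average", "minrank", "rerank")) {
  method <- match.arg(method)
  if (!setequal(fpList$moleculeId, isoList$moleculeId) ||
      nrow(fpList) != nrow(isoList))
    stop("the two rankings must cover the same candidate set")
  idx <- match(fpList$moleculeId, isoList$moleculeId)
  df <- data.frame(moleculeId = fpList$moleculeId,
                   fpRank = fpList$rank,
                   isoRank = isoList$rank[idx],
                   fpScore = fpList$logScore,
                   isoScore = isoList$logScore[idx],
                   stringsAsFactors = FALSE)
  o <- switch(method,
    average = order((df$fpRank + df$isoRank) / 2, df$moleculeId),
    minrank = order(pmin(df$fpRank, df$isoRank), df$moleculeId),
    rerank  = order(-df$isoScore, -df$fpScore, df$moleculeId))
  df <- df[o, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  attr(df, "queryId") <- attr(fpList, "queryId")
  attr(df, "method") <- method
  df
}
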