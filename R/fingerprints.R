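#' @include AllGenerics.R
NULL

#' Compute 528-bit substructure fingerprints
#'
#' Computes the concatenated OpenBabel fingerprint families FP3 (55 bits),
#' FP4 (307 bits) and MACCS (166 bits) for each input structure, 528 bits
#' in total, encoded ±1 (+1 = substructure key present). OpenBabel returns
#' word-padded bit vectors; only the documented leading bits of each family
#' are kept, in the frozen order of [fingerprintKeyNames()].
#'
#' @param structures character vector of SMILES strings, or the text of an
#'   SDF file when `format = "sdf"`.
#' @param ids optional molecule identifiers (defaults to SMILES titles or
#'   running numbers).
#' @param format `"smiles"` (default) or `"sdf"`.
#' @return Integer matrix (molecules x 528) over {+1, -1}; rownames are the
#'   ids, colnames the key names. Attribute `schemaHash` carries the
#'   fingerprint-schema hash.
#' @examples
#' \donttest{
#' fp <- computeFingerprints(c(benzene = "c1ccccc1", ethane = "CC"))
#' dim(fp)  # 2 x 528
#' }
#' @export
computeFingerprints <- function(structures, ids = NULL, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "sdf") {
    mols <- tryCatch(
      ChemmineOB::forEachMol("SDF", paste(structures, collapse = "\n"), identity),
      error = function(e) stop("failed to parse SDF input: ", conditionMessage(e)))
    if (is.null(ids)) ids <- sprintf("molecule_%03d", seq_along(mols))
  } else {
    if (is.null(ids)) {
      ids <- names(structures)
      if (is.null(ids)) ids <- sprintf("molecule_%03d", seq_along(structures))
    }
    mols <- vector("list", length(structures))
    for (i in seq_along(structures)) {
      mols[[i]] <- tryCatch(
        ChemmineOB::forEachMol("SMILES", structures[[i]], identity)[[1]],
        error = function(e) stop("cannot generate a fingerprint for molecule '",
                                 ids[i], "': unparseable structure"))
    }
  }
  fams <- names(.fpFamilies)
  blocks <- lapply(fams, function(fam) {
    raw <- ChemmineOB::fingerprint_OB(mols, fam)
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
    raw[, seq_len(.fpFamilies[[fam]]), drop = FALSE]
  })
  fp <- do.call(cbind, blocks)
  fp <- matrix(ifelse(fp != 0, 1L, -1L), nrow = length(mols))
  dimnames(fp) <- list(ids, fingerprintKeyNames())
  attr(fp, "schemaHash") <- fingerprintSchemaHash(fingerprintKeyNames())
  fp
}

#' Hash of a fingerprint key schema
#'
#' Trained models and candidate databases both record this hash of their
#' (ordered) fingerprint key names; retrieval refuses to score when the
#' hashes disagree, so bit order can never silently differ between the two.
#'
#' @param keyNames character vector of key names in their frozen order.
#' @return character(1) hash.
#' @export
fingerprintSchemaHash <- function(keyNames) {
  digest::digest(paste(keyNames, collapse = "|"), algo = "xxhash64",
                 serialize = FALSE)
}

#' Mask of effective fingerprint bits
#'
#' A bit that is present in every training molecule (all +1) or absent
#' from all of them (all -1) carries no information for training and is
#' removed. The mask keeps exactly the columns where both classes occur.
#'
#' @param trainingFps ±1 matrix, one row per training molecule (or
#'   spectrum), equal-length rows.
#' @return Named logical vector over columns; `TRUE` = keep. Attribute
#'   `mEffective` gives the kept-bit count.
#' @export
effectiveBitMask <- function(trainingFps) {
  if (is.null(dim(trainingFps)) || nrow(trainingFps) < 2)
    stop("need at least two fingerprint vectors to assess effectiveness")
  keep <- apply(trainingFps, 2, function(col) {
    any(col == 1L) && any(col == -1L)
  })
  names(keep) <- colnames(trainingFps)
  attr(keep, "mEffective") <- sum(keep)
  keep
}

#' Tanimoto similarity of two fingerprint vectors
#'
#' The Tanimoto (Jaccard) coefficient on the positive-bit sets:
#' `|A intersect B| / |A union B|` where A, B are the sets of +1 bits.
#' Two all-negative vectors have identical (empty) positive sets and are
#' scored 1 with a message.
#'
#' @param a,b ±1 vectors of equal length.
#' @return numeric in \[0, 1\].
#' @examples
#' fingerprintSimilarity(c(1, 1, -1), c(-1, 1, 1))  # 1/3
#' @export
fingerprintSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  pa <- a == 1L; pb <- b == 1L
  un <- sum(pa | pb)
  if (un == 0) {
    message("both fingerprints are all-negative; similarity defined as 1")
    return(1)
  }
  sum(pa & pb) / un
}

## --- Candidate database I/O ---------------------------------------------

#' Construct a CandidateSet
#'
#' @param ids character molecule identifiers.
#' @param exactMass numeric neutral monoisotopic masses (Da).
#' @param fingerprints ±1 matrix with key names as colnames, one row per
#'   molecule.
#' @param formula optional elemental formulas.
#' @return A [CandidateSet-class].
#' @export
CandidateSet <- function(ids, exactMass, fingerprints,
                         formula = rep(NA_character_, length(ids))) {
  storage.mode(fingerprints) <- "integer"
  new("CandidateSet", ids = as.character(ids), exactMass = as.numeric(exactMass),
      formula = as.character(formula), fingerprints = fingerprints)
}

#' Read / write a precomputed candidate table
#'
#' Tab-separated text with a `# schema_hash:` comment line and columns
#' `id`, `exact_mass`, `formula`, `fingerprint`, where `fingerprint` is a
#' string over `{0,1}` in the frozen key order (1 = bit +1). Key names are
#' stored in a second comment line.
#'
#' @param path file path.
#' @param candidates a [CandidateSet-class].
#' @return `readCandidateTable` returns a [CandidateSet-class].
#' @export
readCandidateTable <- function(path) {
  lines <- readLines(path)
  hashLine <- grep("^# schema_hash:", lines, value = TRUE)
  keyLine <- grep("^# keys:", lines, value = TRUE)
  if (!length(hashLine) || !length(keyLine))
    stop("candidate table lacks the schema header comments")
  hash <- trimws(sub("^# schema_hash:", "", hashLine[1]))
  keys <- strsplit(trimws(sub("^# keys:", "", keyLine[1])), ",", fixed = TRUE)[[1]]
  if (fingerprintSchemaHash(keys) != hash)
    stop("candidate table schema hash does not match its key list")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "character",
                                          "character"))
  bits <- t(vapply(strsplit(tab$fingerprint, ""), function(ch)
    ifelse(ch == "1", 1L, -1L), integer(length(keys))))
  if (length(keys) == 1) bits <- matrix(bits, ncol = 1)
  colnames(bits) <- keys
  CandidateSet(tab$id, tab$exact_mass, bits,
               formula = ifelse(tab$formula == "NA", NA_character_, tab$formula))
}

#' @rdname readCandidateTable
#' @export
writeCandidateTable <- function(candidates, path) {
  keys <- colnames(candidates@fingerprints)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# schema_hash:", fingerprintSchemaHash(keys)), con)
  writeLines(paste0("# keys: ", paste(keys, collapse = ",")), con)
  writeLines("id\texact_mass\tformula\tfingerprint", con)
  fpStr <- apply(candidates@fingerprints, 1, function(row)
    paste(ifelse(row == 1L, "1", "0"), collapse = ""))
  writeLines(sprintf("%s\t%.10f\t%s\t%s", candidates@ids,
                     candidates@exactMass, candidates@formula, fpStr), con)
  invisible(path)
}

#' Load a candidate database from an SDF file
#'
#' Structures are parsed with OpenBabel; fingerprints, exact masses and
#' formulas are computed on load. Molecules whose structures cannot be
#' parsed (no generable fingerprint) are excluded with a warning.
#'
#' @param path SDF file path.
#' @return A [CandidateSet-class] over the 528-key schema.
#' @export
readCandidateSDF <- function(path) {
  text <- paste(readLines(path), collapse = "\n")
  mols <- tryCatch(ChemmineOB::forEachMol("SDF", text, identity),
                   error = function(e) stop("failed to parse SDF: ",
                                            conditionMessage(e)))
  props <- ChemmineOB::prop_OB(mols)
  ids <- props$title
  ids[!nzchar(ids)] <- sprintf("molecule_%03d", which(!nzchar(ids)))
  mass <- ChemmineOB::exactMass_OB(mols)
  ok <- is.finite(mass) & mass > 0
  if (any(!ok))
    warning(sum(!ok), " SDF entries without a usable structure were excluded")
  fp <- computeFingerprints(props$cansmi[ok], ids = ids[ok])
  CandidateSet(ids[ok], mass[ok], fp, formula = props$formula[ok])
}
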