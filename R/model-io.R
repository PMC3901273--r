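#' @include learner.R
NULL

#' Write a trained model as a versioned directory bundle
#'
#' The bundle is plain text: `model.yaml` (format version, seed, kernel
#' parameters, schema hash), `keys.txt` (the frozen key order),
#' `mask.tsv`, `reliability.tsv`, `bit_meta.tsv` (per-bit constant flag,
#' bias, C), `bit_coefficients.tsv` (long table of support-vector dual
#' coefficients), `selfsim.tsv` (per-variant raw self-similarities of the
#' training spectra) and `spectra.massbank` (the training spectra as
#' MassBank records). No timestamps are written, so retraining with the
#' same seed reproduces the bundle byte for byte.
#'
#' @param model a [FingerprintModel-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [readFingerprintModel()]
#' @export
writeFingerprintModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- model@kernelParams
  yaml::write_yaml(list(
    format_version = model@version,
    seed = model@seed,
    schema_hash = model@schemaHash,
    sigma_mass = p@sigmaMass,
    sigma_intensity = p@sigmaIntensity,
    variants = as.list(p@variants),
    normalize = p@normalize,
    n_training_spectra = length(model@trainingSpectra),
    n_effective_bits = sum(model@mask)
  ), file.path(dir, "model.yaml"))

  writeLines(model@keyNames, file.path(dir, "keys.txt"))
  writeLines(c("key\tkeep",
               sprintf("%s\t%d", model@keyNames, as.integer(model@mask))),
             file.path(dir, "mask.tsv"))
  effKeys <- model@keyNames[model@mask]
  writeLines(c("key\tw",
               sprintf("%s\t%.15g", effKeys, model@reliability)),
             file.path(dir, "reliability.tsv"))

  meta <- vapply(seq_along(model@bitModels), function(jj) {
    m <- model@bitModels[[jj]]
    sprintf("%s\t%d\t%.15g\t%.15g\t%.15g", effKeys[jj],
            as.integer(m$constant),
            if (is.na(m$value)) 0 else m$value, m$bias, m$C)
  }, character(1))
  writeLines(c("key\tconstant\tvalue\tbias\tC", meta),
             file.path(dir, "bit_meta.tsv"))

  coefLines <- unlist(lapply(seq_along(model@bitModels), function(jj) {
    m <- model@bitModels[[jj]]
    if (m$constant || !length(m$support)) return(character(0))
    sprintf("%s\t%s\t%.15g", effKeys[jj],
            model@trainingIds[m$support], m$alphaY)
  }))
  writeLines(c("key\tsupport_id\talpha_y", coefLines),
             file.path(dir, "bit_coefficients.tsv"))

  selfLines <- vapply(seq_along(model@trainingIds), function(i)
    paste(c(model@trainingIds[i], model@moleculeOf[i],
            sprintf("%.15g", model@selfSim[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("id", "molecule", colnames(model@selfSim)),
                     collapse = "\t"), selfLines),
             file.path(dir, "selfsim.tsv"))

  recs <- vapply(seq_along(model@trainingSpectra), function(i)
    writeMassBankRecord(model@trainingSpectra[[i]],
                        accession = model@trainingIds[i]), character(1))
  writeLines(paste(recs, collapse = "\n"), file.path(dir, "spectra.massbank"))
  invisible(dir)
}

#' Read a model bundle written by [writeFingerprintModel()]
#'
#' @param dir bundle directory.
#' @return A [FingerprintModel-class].
#' @export
readFingerprintModel <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  params <- KernelParams(sigmaMass = meta$sigma_mass,
                         sigmaIntensity = meta$sigma_intensity,
                         variants = unlist(meta$variants),
                         normalize = meta$normalize)
  keys <- readLines(file.path(dir, "keys.txt"))
  if (fingerprintSchemaHash(keys) != meta$schema_hash)
    stop("model bundle is corrupt: key list does not match its schema hash")
  maskTab <- utils::read.table(file.path(dir, "mask.tsv"), header = TRUE,
                               sep = "\t", colClasses = c("character", "integer"))
  mask <- as.logical(maskTab$keep[match(keys, maskTab$key)])
  relTab <- utils::read.table(file.path(dir, "reliability.tsv"), header = TRUE,
                              sep = "\t", colClasses = c("character", "numeric"))
  effKeys <- keys[mask]
  reliability <- relTab$w[match(effKeys, relTab$key)]

  spectra <- readMassBankFile(file.path(dir, "spectra.massbank"))
  selfTab <- utils::read.table(file.path(dir, "selfsim.tsv"), header = TRUE,
                               sep = "\t", check.names = FALSE,
                               colClasses = "character")
  ids <- selfTab$id
  spectra <- spectra[ids]
  moleculeOf <- selfTab$molecule
  selfSim <- as.matrix(vapply(params@variants, function(v)
    as.numeric(selfTab[[v]]), numeric(length(ids))))
  if (length(ids) == 1) selfSim <- matrix(selfSim, nrow = 1,
                                          dimnames = list(NULL, params@variants))

  bitMeta <- utils::read.table(file.path(dir, "bit_meta.tsv"), header = TRUE,
                               sep = "\t",
                               colClasses = c("character", "integer",
                                              "numeric", "numeric", "numeric"))
  coefTab <- utils::read.table(file.path(dir, "bit_coefficients.tsv"),
                               header = TRUE, sep = "\t",
                               colClasses = c("character", "character",
                                              "numeric"))
  bitModels <- lapply(seq_along(effKeys), function(jj) {
    key <- effKeys[jj]
    row <- bitMeta[match(key, bitMeta$key), ]
    if (row$constant == 1L)
      return(list(constant = TRUE, value = row$value, alphaY = numeric(0),
                  support = integer(0), bias = row$bias, C = row$C,
                  bitIndex = which(keys == key)))
    sel <- coefTab$key == key
    list(constant = FALSE, value = NA_real_,
         alphaY = coefTab$alpha_y[sel],
         support = match(coefTab$support_id[sel], ids),
         bias = row$bias, C = row$C, bitIndex = which(keys == key))
  })

  new("FingerprintModel",
      version = as.character(meta$format_version),
      kernelParams = params,
      keyNames = keys,
      mask = mask,
      reliability = reliability,
      bitModels = bitModels,
      trainingSpectra = spectra,
      trainingIds = ids,
      moleculeOf = moleculeOf,
      selfSim = selfSim,
      schemaHash = meta$schema_hash,
      seed = as.integer(meta$seed))
}
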