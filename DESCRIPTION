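Package: fingerMS
Title: Metabolite Identification by Fingerprint Prediction from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning framework for metabolite identification from
    tandem mass spectrometry data. Spectra are compared with closed-form
    probability product kernels (peaks, mass-loss and mass-difference
    variants) over Gaussian peak models; one support vector machine per
    molecular substructure fingerprint bit (OpenBabel FP3/FP4/MACCS, 528
    bits) predicts the fingerprint vector of an unknown compound, and
    candidate molecules from a user-supplied database are filtered by a
    ppm mass window and ranked by a reliability-weighted Poisson-binomial
    likelihood of their fingerprints. Includes MS1 isotope-pattern
    simulation from molecular formulas with kernel-based pattern matching
    and rank-aggregation fusion, molecule-stratified cross-validation for
    per-bit reliability estimation, a seeded synthetic-world generator for
    end-to-end validation, and command-line entry points for training,
    querying and batch evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    kernlab,
    ChemmineOB,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'kernels.R'
    'isotopes.R'
    'synthetic.R'
    'retrieval.R'
    'learner.R'
    'model-io.R'
    'cli.R'
    'constants.R'
    'evaluate.R'
    'fingerMS-package.R'
    'fingerprints.R'
    'spectra-io.R'
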