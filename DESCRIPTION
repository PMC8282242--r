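Package: mammclock
Title: Methylation-Based Age Clocks and Epigenome-Wide Association for
    Mammalian Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds DNA-methylation age estimators (epigenetic clocks) from
    normalized beta-value matrices by elastic-net penalized regression with
    a bespoke coordinate-descent solver, glmnet-style lambda paths and
    internal 10-fold cross-validation for penalty selection.  Supports
    log-linear and relative-age transformations of the dependent variable,
    leave-one-out and species-stratified 10-fold cross-validation,
    epigenetic age acceleration, epigenome-wide association screening for
    age and sex, Stouffer meta-analysis across cohorts, cross-species
    concordance labelling, genomic-context summaries, random-forest
    species/sex integrity checks, and a synthetic mammalian-array data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
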