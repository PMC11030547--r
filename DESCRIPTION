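Package: diage
Title: Inflammaging Analysis and an Inflammatory-Age Clock for Drosophila RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inflammaging (the chronic age-associated rise
    of innate-immune gene expression) in Drosophila bulk RNA-Seq. Implements the
    sex-stratified AGE-Index (old/young expression ratio) with marker ranking and
    cross-dataset intersection, classification of shared versus female-skewed
    inflammaging patterns, log2 female-to-male expression bias, and the DiAge
    inflammatory-age clock: an elastic-net regression on min-max normalized
    expression fitted by coordinate descent with cross-validated penalty
    selection, resampling assessment, and group comparison of predicted ages.
    Includes a synthetic cohort generator with known ground truth that emulates
    the statistical structure of aging fly transcriptomes (right-skewed age
    distributions, multiplicative inflammaging trends, sex-biased baselines,
    log-normal noise, per-sample TPM renormalization), gene-set
    over-representation by the hypergeometric test, and a reproducible
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
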