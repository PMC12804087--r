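Package: cryptsel
Title: Selection and Decay of Driver Mutations in Primed Intestinal Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies selection on cancer-driver mutations in mutagenized
    intestinal epithelium. Estimates 96-channel trinucleotide mutational
    signatures with opportunity normalization, enumerates coding consequences
    to derive expected driver-mutation probabilities, computes observed/expected
    selection ratios with chi-squared tests for beta-catenin degron mutations and
    binned APC truncations, models neutral stem-cell drift in intestinal crypts
    as the null for tumour decay under rescue protocols, scores human APC
    20-amino-acid-repeat retention stratified by KRAS status, orders APC and
    KRAS mutations from variant allele frequencies, and generates synthetic
    mutation catalogs, cohorts and polyp tables with injected selection for
    end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
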