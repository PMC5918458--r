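Package: exat
Title: Exact Gene-Level Association Tests for Small-Sample Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Gene-level case/control association testing for sequencing
    studies too small for asymptotic burden or variance-component tests.
    Each subject's genotypes over a gene's variants are laid out as an
    SNV-by-minor-allele-count contingency table whose exact null, with all
    margins fixed, is multiple hypergeometric; the generalized
    Cochran-Mantel-Haenszel (GCMH) statistic is computed separately in
    cases and controls and the log-ratio of the two is tested by label
    permutation, with a moment-matched normal approximation as a fast
    alternative and Fisher's exact test as the fallback for single-variant
    genes. Includes readers for VCF and plain-text genotype matrices, a
    synthetic genotype/phenotype generator, and a type-I-error simulation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
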