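Package: samepoptest
Title: Falsification Test for the Two-Sample Mendelian Randomisation
    Same-Population Assumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether two genome-wide association studies (GWAS) can be
    treated as samples from the same population, a requirement of two-sample
    Mendelian randomisation. For a phenotype measured in both samples, the
    per-variant difference in allele effect estimates is tested against zero
    with a z-test; multiple independent variants are combined by fixed-effects
    inverse-variance meta-analysis of the differences and by Fisher's method.
    Includes harmonisation of effect alleles between the two studies (sign
    flips, strand resolution, palindromic-variant handling), a numeric
    scale-mismatch diagnostic, readers and writers for tab-separated GWAS
    summary statistics, and a simulator of sex-structured effect modification
    for characterising the test's power and type-I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
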