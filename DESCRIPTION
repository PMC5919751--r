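Package: abbababa
Title: Extended D-Statistic (ABBA-BABA Test) for Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Four-population test for admixture (Patterson's D / ABBA-BABA
    test) computed directly from per-site read counts, so that all reads of
    multiple individuals per population contribute without genotype calling.
    Population allele frequencies are estimated with depth-dependent
    minimal-variance weights, the statistic is normalised with a weighted
    block-jackknife standard error, type-specific sequencing errors can be
    estimated from a (contaminated, error-free, outgroup) trio of genomes and
    removed from the pattern probabilities, and gene flow from a fifth,
    external population can be corrected for or its admixture proportion
    estimated. Includes a synthetic-data simulator (tree-structured drift,
    pulse migration, Poisson read depth, injected base-type errors) for
    validation, readers for count tables, samtools mpileup text and
    ms-format haplotypes, and a small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
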