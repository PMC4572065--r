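Package: ecotypeSNP
Title: SNP Array Design, Validation and Population Structure for Ecotype
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating a fixed-content SNP
    genotyping array from transcriptome variant calls and for analysing
    the resulting codominant genotype data in hierarchically structured
    ecotype collections.  Implements the probe-selection filter cascade
    (coverage, quality, shared polymorphism, contig annotation, marker
    spacing, flanking sequence, designability), the marker-validation
    cascade (cluster quality, missingness, Mendelian trio errors, minor
    allele frequency, exact heterozygote-excess test on the Levene
    conditional distribution), allele-frequency encoding with principal
    component analysis and geographic correlation, and distance-based
    hierarchical AMOVA with Phi statistics and permutation tests.  A
    Balding-Nichols simulator generates genotype matrices, mapping
    families, variant reports and cluster statistics with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
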