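Package: ovpdt
Title: Ordered Subset - Variable Threshold Pedigree Disequilibrium Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Family-based association testing for sequencing data that combines
    common and rare variants in a region while accounting for the direction of
    effects. Common variants are prioritised by genotypic relative risks
    estimated from parental mating types and scanned with an ordered-subset
    algorithm; rare variants enter through a variable minor-allele-frequency
    threshold burden of pedigree disequilibrium test (PDT) statistics. The two
    components are combined and assessed with an adaptive, linkage- and
    LD-preserving sign-flip permutation test. Includes readers for linkage PED
    and VCF/FAM nuclear-family data, a calibrated coalescent simulator of family
    sequencing cohorts under a logistic penetrance disease model, and a harness
    for type I error and power experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
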