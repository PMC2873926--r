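Package: bgcscan
Title: Fixation-Bias Tests and Sweep Scans for GC-Biased Gene Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect GC-biased (weak-to-strong) fixation bias in
    resequencing data around candidate regions such as Human Accelerated
    Regions. Implements mutation-class-partitioned derived allele frequency
    spectra with hypergeometric projection, Mann-Whitney U spectrum-offset
    and McDonald-Kreitman-like polymorphism/divergence tests with masking
    scans, a composite-likelihood-ratio selective sweep scan with
    simulation-based p-values, neutral coalescent and phylogenetic
    calibration simulators, a forward Wright-Fisher simulator of biased
    gene conversion modeled as genic selection, and a synthetic study
    generator producing fixture data with the statistical shape of a
    targeted-resequencing experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
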