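Package: phagehost
Title: Capsid Packing Density, Cophylogeny, and Codon Selection Analyses for Phage Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for characterising newly isolated tailed
    bacteriophages and their bacterial hosts. Implements an icosahedral capsid
    model for genome packing density from transmission electron microscopy
    measurements (radius-convention conversions, shell-thickness correction and
    calibration); a ParaFit-style host-parasite cophylogeny permutation test
    built on principal coordinates analysis with Cailliez correction; pairwise
    dN/dS estimation by the Li-Wu-Luo degeneracy-class method together with a
    bootstrap codon-based z-test of strict neutrality; fragment-based average
    nucleotide identity with the ICTV species-demarcation rule; orthogroup
    host-exclusivity and gene-duplication filters; and complete-genome triage
    from assembly metadata. Seeded synthetic-data generators reproduce the
    statistical structure each stage assumes, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
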