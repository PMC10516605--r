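Package: msifsm
Title: Microsatellite Instability and Frameshift Mutation Calling from
    Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of microsatellite instability (MSI) and coding
    mononucleotide-repeat frameshift mutations from targeted amplicon
    sequencing and capillary-electrophoresis fragment analysis. Provides a
    PCR-stutter read simulator for mononucleotide-repeat amplicon panels, a
    primer-trimming and repeat-length extraction layer, a Weibull
    background-error model for indel variant-allele-frequency positivity
    calling with Benjamini-Hochberg false-discovery-rate control, fragment
    trace peak calling with MSI-H/MSS classification over a marker panel, and
    a read-frequency hotspot mutation caller for amplicon resequencing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
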