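Package: plastcomp
Title: Comparative Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite structure (LSC/SSC and the
    inverted repeats) with junction gene reports, uncorrected p-distance and
    per-noncoding-region variability profiling, outgroup-polarized
    substitution and indel spectra with slipped-strand (homopolymer / tandem
    repeat) context classification, genome-size decomposition into genes,
    introns and intergenic spacers, and Tajima's one-degree-of-freedom
    relative rate test. Includes a plastome evolution simulator that emits
    true alignments and per-branch event logs, so every analysis stage can be
    validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
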