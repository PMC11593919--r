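Package: plastomics
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for comparative plastome (chloroplast genome) analysis:
    reading and writing annotated GenBank records, sequence-based detection of
    the quadripartite structure (LSC/IRb/SSC/IRa) with inverted-repeat junction
    reports and regional GC content, codon-usage-bias statistics (codon counts,
    RSCU, positional GC, Wright's effective number of codons with the expected
    null curve, PR2 coordinates, neutrality regression), MISA-style
    microsatellite and REPuter-style dispersed-repeat detection with genomic
    context classification, per-locus nucleotide diversity with
    hypervariable-region calling, pairwise Ka/Ks estimation (Nei-Gojobori 1986
    with Jukes-Cantor correction), and a synthetic plastome simulator with
    machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
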