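Package: plastidcomp
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of complete chloroplast
    (plastid) genomes: detection of the quadripartite LSC/IRb/SSC/IRa
    structure and inverted-repeat junctions with flanking-gene context,
    perfect microsatellite (SSR) scanning with motif canonicalization and
    regional classification, alignment-based divergence statistics
    (variable and parsimony-informative sites, nucleotide diversity,
    Watterson's theta, sliding windows, hypervariable-region ranking,
    pairwise indel and substitution counts, per-region variability), and
    pairwise dN/dS estimation with the Nei-Gojobori (1986) pathway method.
    A synthetic plastome generator with substitution/indel event logs
    provides exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
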