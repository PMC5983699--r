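Package: plastcomp
Title: Comparative Plastome Analysis: Repeats, Divergence Hotspots, Gene
    Loss and Selection Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid genomes
    (plastomes), modelled on the comparative workflows used for
    inverted-repeat-lacking legume plastomes. Reads annotated GenBank
    flat files, extracts homologous coding, intron and intergenic-spacer
    regions, computes composition and codon-usage statistics, detects
    microsatellites (SSRs), dispersed (forward/palindromic) and tandem
    repeats with explicit unit-count and score thresholds, screens
    intergenic spacers for divergence hotspots with Kimura 2-parameter
    distances and a mean + 2 SD rule, builds gene presence/absence
    matrices with monophyly checks of losses, runs neighbor-joining
    phylogenies with bootstrap support, and performs a pairwise
    Nei-Gojobori (1986) Ka/Ks selection screen. A synthetic plastome
    generator with full ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
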