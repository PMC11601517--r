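Package: cleavemap
Title: Simulation and Analysis of Strand-Specific Nuclease Cleavage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse nucleotide-resolution,
    strand-specific DNA cleavage maps of the kind produced by end-capture
    sequencing of topoisomerase-like double-strand breaks with 2-nt 5'
    overhangs. Includes a sequence-biased cleavage library simulator with
    library-prep artifacts (nicks, incomplete fill-in, uniform background),
    strand-map construction with RPM normalisation, masking and Hann
    smoothing, cross-correlation overhang-polarity testing, threshold peak
    calling with a fill-in artifact filter, dyad-centred base-composition
    and GC-corrected sequence-logo analysis, degenerate motif scanning,
    anchored profile averaging, and equilibrium/kinetic models of dimeric
    enzyme assembly and biphasic cleavage kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
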