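Package: g4tune
Title: Design and Evaluation of Synthetic G-Quadruplex Expression Controllers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing synthetic G-quadruplex (G4) regulatory
    components that tune mammalian recombinant protein expression at the
    transcriptional (DNA) and translational (RNA) level. Provides
    full-factorial motif library enumeration with loop-composition rules,
    a putative quadruplex-forming sequence (PQS) scanner and G4-disabled
    mutant designer, assembly of motifs into a standardized core
    promoter/5'UTR expression chassis with strand-aware insertion
    semantics and upstream start-codon screening, a three-feature linear
    model of component activity, a multiplicative two-level (DNA+RNA)
    synergy predictor, a heavy-chain:light-chain expression-ratio design
    space for multichain products, and a synthetic-data generator that
    emulates relative expression unit (REU) measurements for end-to-end
    testing without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
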