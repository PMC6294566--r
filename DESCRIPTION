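Package: ringforge
Title: Terminal-Hairpin Design of Single-Stranded DNA Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for preparative synthesis of single-stranded DNA
    rings by splint-mediated T4 ligation. Implements the terminal-hairpin
    strategy: a nearest-neighbor thermodynamic engine for perfect-stem DNA
    hairpins, exhaustive hairpin scanning of linear oligonucleotides,
    enumeration of circular permutations of a target ring with positional and
    stability filters on the terminal hairpin, splint design, a two-state
    folded/open equilibrium model predicting the maximum preparative
    concentration, screening of sequence collections for strategy-usable
    hairpins, and gel band-intensity quantification (conversion, selectivity,
    yield).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
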