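Package: bapfish
Title: Interpretation of Unbalanced MYC Break-Apart FISH Results from
    Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconcile MYC break-apart (BAP) interphase FISH
    results with whole-genome-sequencing derived structural variants in
    aggressive B-cell lymphoma. Parses and re-emits ISCN "nuc ish"
    nomenclature for the two-colour BAP assay, simulates the red/green/fusion
    signal pattern implied by a rearranged genome built from breakpoint
    junctions and copy-number segments, classifies patterns as
    RGF/RF/GF/fusion copy-number changes, reconciles observed against
    predicted patterns, and renders a guarded clinical interpretation of
    unbalanced results. Ships a 14-case validation set, a seeded generator
    of rearrangement archetypes with known truth, VCF/BED/SEG readers and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
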