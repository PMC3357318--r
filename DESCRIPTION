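Package: alusleuth
Title: Alu Subfamily Inference and Source-Element Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Alu/SINE subfamily structure from diagnostic mutations,
    identifies and ranks candidate source ("driver") elements using
    private-mutation counts and retrotransposition-competence hallmarks
    (target site duplications, poly(A) tail integrity, Pol III promoter and
    terminator context), and reconstructs relative insertion order and ages
    from CpG-aware substitution counts, allele frequencies and cross-species
    presence/absence on a dated tree. Ships a stealth-driver amplification
    simulator that generates truth-tagged element copies under CpG-biased
    neutral mutation and Wright-Fisher drift so every inference stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
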