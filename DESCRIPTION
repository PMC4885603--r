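Package: knotann
Title: Pseudoknot-Aware Annotation of RNA Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates RNA secondary structures given as base-pair lists:
    maximal stems, elementary closed regions (classical and pseudoknotted),
    a generalized loop decomposition that works identically for
    pseudoknot-free and pseudoknotted structures, three-level topological
    pseudoknot signatures with recognition of named classes (H-knot,
    kissing hairpins, triple knot), and a taxonomy of tertiary base-base
    interactions by secondary-structure context and locality. Reads and
    writes extended dot-bracket, CT, BPSEQ and tabular base-pair formats,
    ships deterministic fixtures and a seeded random structure generator
    with brute-force oracles for validation, and provides batch
    annotation, collection statistics and a disjunctive-normal-form
    search over annotations, both as R functions and as a command-line
    tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
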