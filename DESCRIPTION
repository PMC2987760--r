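Package: sigreverse
Title: Directional Gene-Set Overlap and Drug-Disease Signature Reversal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether a drug-response gene set counteracts
    pooled disease expression signatures. Pools directional (up/down)
    differential-expression signatures across studies, maps a drug gene set
    across species through a local homology table, tests directional overlap
    with exact hypergeometric enrichment and depletion probabilities,
    extracts the counteracting commonality genes, and scans a GMT pathway
    collection for over-representation of those genes against the
    disease-upregulated background. Includes an exact-combinatorial
    synthetic-data generator that plants prescribed overlap cardinalities
    and pathway memberships so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
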