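Package: nucvote
Title: Consensus Nuclear-Localization Calling and NLS/NES Signal Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building a consensus nuclear-localization call for
    plant proteomes from several subcellular-prediction tools, scanning
    protein sequences for classical nuclear localization signals (PAT4,
    PAT7, bipartite) and leucine-rich nuclear export signals, benchmarking
    predictions against curated localization evidence, testing category
    composition and GO-term enrichment, and assessing splice-isoform
    localization concordance. Includes a synthetic proteome generator with
    planted motifs and controlled per-tool error rates so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
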