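Package: ppminet
Title: Substance Co-Mention Networks from Social Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines self-reported medication and supplement use from
    Reddit-style post dumps. Extracts substance mentions with a
    negation-aware dictionary matcher and fuzzy entity linking, builds a
    positive pointwise-mutual-information (PPMI) co-occurrence network
    over per-post substance sets, detects substance communities with a
    seeded Leiden algorithm under weighted modularity, and reports
    cluster composition and degree centrality. Ships a synthetic corpus
    generator with planted substance clusters and gold annotations so
    the whole pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
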