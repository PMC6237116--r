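Package: mirtfnet
Title: Cancer-Specific miRNA-TF Co-Regulatory Network Construction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds typed miRNA-transcription-factor regulatory networks from
    tab-separated edge tables (TF-gene, TF-miRNA, miRNA-gene, miRNA-TF),
    screens them to cancer-relevant interactions, enumerates co-regulatory
    pairs and the three classes of three-node feed-forward loops (TF-FFL,
    miRNA-FFL, composite-FFL), refines motifs against matched gene and miRNA
    expression matrices using Spearman correlation with p-value, magnitude and
    sign rules, and analyses the resulting co-regulatory network with degree,
    HITS hub/authority scores and hypergeometric set over-representation.
    Includes a synthetic-data generator with planted motifs and planted
    correlation structure so the whole pipeline is testable without external
    databases, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
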