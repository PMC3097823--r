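Package: mlnet
Title: Minimal Lateral Networks for Hidden Lateral Transfer in Binary
    Character Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects hidden lateral transfer (lexical borrowing among
    languages, horizontal gene transfer among genomes) in binary
    presence/absence characters evolving along a rooted reference tree.
    Implements bounded-origin gain-loss parsimony (loss-only,
    single-origin and BOR-k borrowing models), model selection by a
    uniformitarian criterion comparing ancestral and contemporary
    inventory sizes, shared-character networks with leading-eigenvector
    modularity community detection, minimal lateral network assembly
    with network statistics, and a seeded gain-loss-borrowing simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
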