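Package: trflptools
Title: Terminal Restriction Fragment Length Polymorphism Profiling of
    Functional Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for terminal restriction fragment length polymorphism
    (T-RFLP) community profiling with functional marker genes such as the
    formyltetrahydrofolate synthetase (FTHFS) gene of acetogenic bacteria.
    Implements degeneracy-aware in silico restriction digestion of
    primer-tagged reference amplicons, ingestion and noise filtering of
    capillary-electrophoresis peak tables, clustering of terminal fragments
    into operational TRF (oTRF) units with a moving-average window,
    matching of experimental oTRF profiles against in silico profiles with
    taxonomic rollup, and principal coordinate ordination of the resulting
    abundance tables. A seeded simulator produces reference databases,
    reactor-style community time series and electropherogram peak tables
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
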