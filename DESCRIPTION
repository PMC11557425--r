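Package: cellulosomics
Title: Comparative-Genomic Classification of Cellulosome-Producing Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based comparative-genomic inference for cellulosome-producing
    bacteria. Parses protein domain-annotation tables (InterProScan dialect)
    into canonical per-protein domain architectures, classifies every
    cohesin-containing protein into one of eight scaffoldin categories via a
    deterministic decision tree, tabulates dockerin-fused and free
    carbohydrate-active enzyme profiles, types organisms as complex, simple or
    scaffoldin-containing cellulosome producers with high/low DocGH-LCB levels,
    audits cohesin-dockerin type complementarity, and rescues
    sequence-divergent cohesin domains from predicted C-alpha structures with a
    fixed-normalization TM-score scorer. A seeded synthetic-data generator
    emulates per-organism domain-architecture tables and decoy folds so every
    stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
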