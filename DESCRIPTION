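Package: metscreen
Title: Analysis of In Vivo Pooled CRISPR Screens for Metastasis Suppressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hit calling for in vivo genome-wide CRISPR knockout screens that
    compare metastatic lesions against matched primary tumors. Provides
    median-of-ratios count normalization, a negative-binomial mean-variance
    model for per-sgRNA paired enrichment and depletion p-values, gene-level
    modified robust rank aggregation (alpha-RRA) with permutation p-values and
    Benjamini-Hochberg FDR, replicate integration into per-gene essentiality
    scores, cross-cell-line concordance, and a lung-versus-liver rank filter
    for organ-specific suppressors. Includes a generative simulator of an
    in vivo screen with transplantation and organ-seeding bottlenecks and
    planted suppressor genes, plus small quantification helpers (RNAscope
    H-score, ChIP percent input, 2^-ddCt relative expression, caliper tumor
    volume, and single-cell migration track statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
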