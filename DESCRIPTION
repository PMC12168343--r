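Package: chromadapt
Title: Windowed ChIP-Seq Enrichment Calling and Spike-In Expression
    Analysis for Chromatin Responses to Nutrient Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse two-condition chromatin immunoprecipitation
    sequencing (ChIP-seq) experiments with a window-based Poisson
    enrichment caller (50-bp tiling, input-derived local background,
    two-neighbor significance rule), gene-anchored signal summaries
    (TSS profiles, body-scaled metagenes, heat-map matrices, difference
    tracks), a random-gene-set resampling null for promoter-proximal
    differential binding, spike-in-normalized RPKM expression
    quantification with fold-change classification and hypergeometric
    category enrichment, and polysome-to-monosome absorbance ratios.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
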