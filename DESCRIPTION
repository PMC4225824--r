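Package: mirdynet
Title: Integrated miRNA-mRNA Dynamic Gene Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers sparse linear ordinary-differential-equation gene
    regulatory networks that integrate miRNA and mRNA time-series
    expression data with prior knowledge. Provides replicate averaging and
    time-series standardisation, differential-expression and
    multi-database miRNA target-prediction filters, Pearson-correlation
    node selection, greedy sparse structure and parameter optimisation
    under a per-series error budget with flexible prior-knowledge
    integration, model selection across an error-budget sweep, and
    noise-resampling validation of edge stability. A synthetic-data module
    generates ground-truth networks and every input artifact the pipeline
    consumes, so structure-recovery performance can be scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
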