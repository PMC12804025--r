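Package: granulekit
Title: Time-Resolved Secretome and Cellular Proteome Analysis of Neutrophil Degranulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for quantifying stimulus-induced protein release
    from neutrophils by combining time-course secretome and cellular proteome
    label-free quantification (DIA LFQ). Provides readers for long-format DIA-NN
    style reports, median and spike-in (external standard) normalization,
    fold-change and relative-percentage trajectory computation, a linear-trend
    release screen with granule annotation and secretion-route summaries, fuzzy
    c-means temporal clustering with automatic cluster-number selection,
    integration of cellular depletion and supernatant release patterns,
    MMP/ADAM sheddase substrate calling from inhibitor experiments, and peptide
    topology mapping onto single-pass membrane protein models. Includes a
    synthetic-data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
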