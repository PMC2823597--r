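Package: agimir
Title: Preprocessing and Replicate-Precision QC for Agilent microRNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads Agilent Feature Extraction (AFE) tab-delimited exports for
    microRNA microarrays, reconstructs the vendor-style total gene signal
    (TGS), and adapts the robust multiarray average (RMA) procedure --
    optional exponential+normal background correction, quantile
    normalization, log2 transformation, replicate-feature collapsing and
    median-polish probe summarization -- to obtain one expression value per
    microRNA per array. Provides four processed signals (nor75, norQ,
    norRMA, norRMAbg), replicate-precision diagnostics (SD-versus-mean
    profiles with natural cubic spline trends, relative log expression
    summaries), detection-flag filtering, and a synthetic AFE data
    generator emulating the Human microRNA Microarray v2.0 layout so the
    full pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    splines,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
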