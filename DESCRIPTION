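Package: lncnet
Title: lncRNA-mRNA Co-Expression and Transcription-Factor Network Analysis
    for Two-Group Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-group single-channel expression
    microarrays profiling both long non-coding RNAs (lncRNAs) and mRNAs:
    quantile normalization, detection-flag filtering, fold-change plus t-test
    differential expression, Pearson lncRNA-mRNA co-expression ranking,
    guilt-by-association functional enrichment and lncRNA-transcription-factor
    inference by hypergeometric target-set overlap, heterogeneous
    lncRNA-target-TF network construction with Cytoscape-compatible export,
    and 2^(-ddCt) qPCR concordance reporting. Includes a latent-factor
    synthetic-data generator with planted differential expression and
    TF-driven co-expression modules for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
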