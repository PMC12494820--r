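Package: tfsignals
Title: Prediction of Transcription Factor Input Signals from Paired
    Transcriptomics and Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic prediction of the small-molecule input signals of
    bacterial transcription factors (TFs). TF activities are inferred from a
    gene expression matrix by signed regulon enrichment with regulatory-network
    subsampling, benchmarked against TF knockout conditions, correlated with
    metabolite abundances by bootstrap Spearman correlation with a median-ROC
    false positive rate threshold and a stability score, and filtered by
    shortest-path distance between each metabolite and the nearest
    TF-regulated reaction in a genome-scale metabolic network. Includes a
    metabolomics preprocessing chain (replicate merging, total ion count
    normalization, coefficient-of-variation filtering, exact-mass annotation)
    and a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
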