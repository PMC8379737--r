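Package: ddinet
Title: Siamese Multi-Head Attention Networks for Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from multi-modal drug
    similarity profiles with a Siamese multi-head self-attention encoder
    trained under a joint classification and contrastive objective. Provides
    builders for Jaccard and Gaussian Interaction Profile (GIP) similarity
    matrices, stratified cross-validation with validation-AUPR model
    selection, ROC/precision-recall evaluation, two modality-importance
    procedures (attention-score aggregation and masking ablation), and a
    synthetic benchmark generator with planted co-feature structure. The
    encoder, losses, analytic gradients and Adam optimizer are implemented
    in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
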