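Package: mdpath
Title: Metapath-Aggregated Graph Attention for Microbe-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts novel microbe-disease associations from a tripartite
    microbe-drug-disease heterogeneous network. Node embeddings are learned
    by a metapath-aggregated graph neural network: metapath instances are
    encoded with a relational-rotation (complex phase) encoder, combined by
    multi-head graph attention within each metapath, and fused across
    metapaths by semantic attention. Associations are scored by
    reconstructing the binary microbe-disease adjacency matrix from the
    learned embeddings. Includes edge-list readers, a planted-block
    synthetic network generator, negative sampling and stratified
    train/validation/test splitting, an Adam training loop with early
    stopping, ablation variants, ROC/PR evaluation, and per-disease
    candidate ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
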