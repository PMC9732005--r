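Package: tdfuse
Title: Tensor-Decomposition Integration of Unmatched Gene Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene expression profiles from independent studies that
    share only their gene universe -- no sample matching and no common labels.
    Each study is compressed to a small genes-by-L latent representation by
    singular value decomposition (or higher-order SVD for multi-condition
    tensors), sign-aligned across studies, stacked into a genes-by-L-by-study
    tensor over a common gene universe, and decomposed by HOSVD. Gene-side
    singular vectors are converted to chi-squared P-values under a Gaussian
    null, Benjamini-Hochberg adjusted, and thresholded to select genes whose
    expression varies consistently across all studies. Also provides sample
    projection onto the shared gene-factor space with a categorical-regression
    screen, drug ranking by nested HOSVD of projected drug-response tensors, a
    single-cell RNA-seq compression path, concatenation-SVD and per-study PCA
    baselines, and synthetic-data generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
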