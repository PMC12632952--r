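Package: dimshift
Title: Dimensions of Visual Similarity, Memory Interference, and
    Hippocampal Pattern Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking dimensions of visual stimulus similarity to
    memory interference and to transformations of fMRI pattern similarity.
    Implements behavioral similarity estimators (associative-memory
    confusability, odd-one-out triplet similarity) with exclusion rules and
    split-half reliability, image-computable similarity metrics (SSIM, GIST)
    plus a generic embedding interface, PCA extraction of orthogonal
    similarity dimensions from stacked pair-by-metric tables, degree
    centrality predictors, cross-run Fisher-z pattern-similarity scores with
    a category baseline, and mixed-effects interaction analyses with linear
    contrasts. A synthetic-data generator plants known latent similarity
    dimensions with training-dependent behavioral and neural couplings so
    that the full inference chain can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
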