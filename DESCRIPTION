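Package: ecgxai
Title: Evaluating Attribution Methods for Deep ECG Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for stress-testing post hoc attribution
    (saliency) methods on one-dimensional deep learning electrocardiogram
    classifiers. Provides a synthetic median-beat ECG generator with planted,
    class-discriminative morphology and ground-truth relevance masks; a compact
    1D residual convolutional network with a fully deterministic forward and
    backward engine; from-scratch implementations of twelve gradient-,
    activation- and Shapley-based attribution methods; Savitzky-Golay map
    smoothing and per-lead correlation scoring; and four evaluation
    experiments: inter-method similarity, self-consistency across random
    initializations, cascading layer randomization, and remove-and-debias
    input perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    withr,
    readr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
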