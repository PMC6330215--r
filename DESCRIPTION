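Package: dynsubgraphs
Title: Dynamic Functional Subgraphs from Sliding-Window Coherence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes dynamic functional connectivity into overlapping
    network subgraphs and time-dependent expression coefficients. Builds
    sliding-window wavelet-coherence multilayer networks from multichannel
    time series, concatenates subjects into a nonnegative cohort matrix,
    factorizes it with a sparsity-penalized nonnegative matrix factorization
    (deterministic NNDSVD initialization, alternating nonnegativity-
    constrained least squares via block principal pivoting), maps subgraphs
    onto an a-priori cognitive-system partition with label-permutation
    nulls, and quantifies expression dynamics (signal energy, histogram
    entropy, temporal derivative) with rank-based group comparisons and
    permutation tests. A synthetic-cohort generator with planted ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
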