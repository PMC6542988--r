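Package: sparsefa
Title: Sparse Direct Feedback Alignment for Training Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Training of fully connected neural networks with backpropagation,
    direct feedback alignment (DFA), and sparse direct feedback alignment
    (SDFA/SSDFA), in which the output error is delivered to hidden neurons
    through fixed random feedback matrices with controlled rank and sparsity.
    Includes construction and measurement of rank- and sparsity-constrained
    feedback matrices, the alignment-angle diagnostic between feedback and
    downstream forward weights, an analytic hardware cost model of reads,
    writes, multiply-accumulate operations and data movement per training
    example, synthetic classification task generators, an IDX-format reader,
    and a rank/sparsity sweep runner with tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
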