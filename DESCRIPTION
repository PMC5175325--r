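Package: pharmRegIRT
Title: Bayesian Item Response Indices of National Pharmaceutical Regulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs national pharmaceutical-regulation indices from binary
    WHO-style survey items using a one-factor Bayesian probit item response
    model fitted by data-augmented Gibbs sampling. Ships the item registries
    for three indices (state regulatory infrastructure, monitoring of the
    private market, public quality control), a synthetic survey generator with
    known ground truth, posterior summaries with weak-item flagging, pairwise
    and group posterior rank probabilities between countries, cross-index
    coefficients of determination with a corner-occupancy diagnostic, and a
    reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    coda,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
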