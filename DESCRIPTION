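Package: dcmig
Title: Markov Blanket Discovery with Cached-Entropy G-Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based Markov blanket discovery on discrete data with the
    IPC-MB algorithm, backed by interchangeable G-test engines: direct counting,
    static and dynamic AD-trees (with most-common-value elision and leaf-lists),
    and a decomposed conditional mutual information engine that computes the G
    statistic from cached joint-entropy terms with no change in value. Includes
    a Bayesian network toolkit (BIF parsing, d-separation, ancestral sampling,
    random network generation) used both to simulate data and to validate
    recovered blankets against graph truth, plus a comparative experiment
    harness reporting CI-test counts and cache hit rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
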