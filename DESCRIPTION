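Package: twinmr
Title: Direction-of-Causation and Mendelian-Randomization Twin Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact covariance-structure implementations of the bivariate
    Direction-of-Causation (DoC) twin model and its polygenic-score
    instrumented extensions (MR-DoC, MR-DoC2), with multigroup normal-theory
    maximum-likelihood fitting to monozygotic/dizygotic twin-pair covariance
    matrices, non-centrality-parameter power analysis for likelihood-ratio
    tests, exact-moment data simulation, and factorial simulation studies of
    measurement-error bias and unshared-environment misspecification bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
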