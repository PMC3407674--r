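Package: streamcds
Title: Real-Time Clinical Decision Support by Data-Stream Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A real-time clinical decision-support engine built on an
    incremental Hoeffding-tree (VFDT) classifier over windowed vital-sign
    streams. Tree leaves carry pointer lists into an append-only historical
    medical-record store via a pointer-to-record mapping table, so a
    classified data unit retrieves similar past cases directly. Ranked
    treatment, diagnosis and prognosis advice is extracted by grouping
    free-text descriptions under a token-set similarity and taking the most
    frequent group; per-leaf results are cached with version-stamped
    invalidation. Doctor feedback is folded in by copy-train-swap so
    classification is never interrupted. Includes a synthetic vital-sign and
    record generator with known ground truth, and a quadratic-form
    (Mahalanobis-type) metric distance as a retrieval baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
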