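Package: deepimmune
Title: Deep-Immune Scoring of Tumor Tissue Maps with Survival Validation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes stroma- and lymphocyte-based prognostic scores from
    patch-grid tissue probability maps of hematoxylin-eosin stained
    whole-slide images of colorectal cancer. Provides the Deep-TSR score
    (stroma fraction of the tumor bed), the Deep-TIL score (mean lymphocyte
    probability within the stroma mask), and their four-level composite
    Deep-immune score; stroma CD3+ T-cell density from immunohistochemistry
    cell detections; a survival validation layer (Kaplan-Meier, log-rank,
    Cox proportional hazards, Harrell's C-index, integrated time-dependent
    AUC over 0-5 years); and a synthetic-data generator so the whole
    pipeline is testable at desk scale without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
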