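Package: hoacompare
Title: Comparative Rule-Based Cortical Parcellation for Human and Macaque
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Machine-readable encodings of the revised Harvard-Oxford cortical
    parcellation ontologies for the human (73 parcellation units) and rhesus
    macaque (40 parcellation units) brains, together with a geometric labeling
    engine that applies the published border rules (limiting sulci, coronal
    limiting planes, derived surface lines) to an annotated hemisphere, a
    cross-species and Brodmann-area equivalence reasoning layer, voxel-count
    regional morphometry, and a synthetic phantom-hemisphere generator with
    analytic ground truth for end-to-end validation without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
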