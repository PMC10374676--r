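Package: hematotox
Title: Mechanistic Prediction of Chemotherapy-Induced Hematotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulates an integrated mechanistic model of human
    hematopoiesis (stem cells, granulopoiesis, thrombopoiesis with
    megakaryocyte ploidy classes and an osteoblast niche, lymphocytes,
    monocytes, G-CSF and TPO feedback) under multi-drug chemotherapy
    exposure (FLOT, FLO/mFOLFOX, FOLFIRINOX), learns individual model
    parameters from first-cycle blood counts by penalized
    virtual-participation likelihood, and predicts and evaluates CTCAE
    toxicity grades for subsequent cycles. Includes linear compartmental
    pharmacokinetic models of the cytotoxic drugs, a synthetic-cohort
    generator emulating the sparse clinical sampling schedule, and
    tidy evaluation and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
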