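Package: reopalg
Title: Reoperation Phenotyping Algorithms for Coded Hospital Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies reoperations after primary fracture surgery in
    longitudinal coded hospital-contact data (NOMESCO procedure and ICD-10
    diagnosis codes, Danish-registry dialect) and classifies their causes
    with stepwise code-set algorithms. Implements anatomical-region and
    laterality matching, a 365-day follow-up window with configurable
    exclusions, a severity hierarchy for competing causes, stepwise
    "or"-composed algorithm construction with kappa-maximal step selection,
    full diagnostic-accuracy statistics (sensitivity, PPV, specificity,
    NPV, exact Clopper-Pearson intervals, Cohen's kappa, balanced-accuracy
    AUC), and a synthetic registry generator with a calibrated coding-error
    model so the whole pipeline is testable without access to real
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
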