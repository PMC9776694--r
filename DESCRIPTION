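Package: airmcdm
Title: Fuzzy Multi-Criteria Ranking of Imaging Modalities for Suspected
    Pediatric Appendicitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analysis toolkit for choosing an abdominal imaging
    modality (ultrasound, non-contrast CT, contrast-enhanced CT, MRI) for
    children with suspected acute appendicitis. Computes the Appendicitis
    Inflammatory Response (AIR) score from clinical findings and stratifies
    patients into low/high probability groups; encodes expert judgments on
    imaging criteria as five-level linguistic triangular fuzzy numbers with
    Yager-index defuzzification; ranks the modalities with PROMETHEE I/II
    outranking flows (Gaussian preference functions) and with the TOPSIS
    closeness coefficient; and reports cross-method rank agreement.
    Includes seed-reproducible generators for linguistic decision matrices
    and synthetic patient cohorts, tidy accessors for all results, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
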