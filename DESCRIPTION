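Package: tamorph
Title: Morphometry and Peritumoral Spatial Analysis of Tumor-Associated
    Macrophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-cell morphometry of manually traced CD163+ macrophage
    outlines (shoelace area, edge-sum perimeter) aggregated by the
    three-zones-of-seven sampling protocol, ROC-derived optimal area
    cutoff separating small from large tumor-associated macrophages
    (S-TAM/L-TAM), Kaplan-Meier / log-rank / bootstrap-validated Cox
    survival analysis of the resulting classes, and density-map/foci
    spatial statistics of L-TAMs in a 500-micrometre peritumoral band.
    Includes a synthetic cohort generator (annotated slides plus linked
    survival outcomes) so the whole pipeline runs and is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    pracma,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
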