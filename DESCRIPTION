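Package: residuomics
Title: Ancient Residue Metabolomics by Untargeted LC-MS Profile Intersection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes plant-species use in archaeological artifacts from
    untargeted LC-MS residue profiles. Implements centroided LC-MS feature
    detection (crop filter, mass detection, chromatogram building, baseline
    cut-off deconvolution, isotopic peak grouping), cross-run join alignment,
    blank-pipe background subtraction, merging of sequential solvent extracts
    into per-sample compound lists, and presence/absence set-intersection
    attribution of an artifact's compound list against experimentally smoked
    reference pipes. Supporting stages include constrained CHNO molecular
    formula prediction with isotope-pattern scoring, biomarker annotation with
    isobar discrimination, Jaccard/NMDS and Pareto-scaled PCA ordination, and
    radiocarbon date calibration. A synthetic-data module generates centroided
    runs with a full ground-truth ledger so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
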