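Package: fatsas
Title: Chest Fat Quantification from CT Volumes via Standardized Anatomic Space
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying thoracic subcutaneous (SAT) and visceral
    (VAT) adipose tissue from CT-like volumes. Implements fat-window
    threshold segmentation with interface-guided SAT/VAT splitting and
    marrow pseudo-fat correction, landmark-calibrated standardized
    anatomic space (SAS) slice mapping, skeleton-normalized fat volume
    and area measures, attenuation-histogram quality parameters, and the
    best-slice search that maximizes area-to-volume correlation across a
    cohort. Includes a seeded synthetic CT phantom generator with full
    ground truth for end-to-end validation, plus a reproducible pipeline
    driver and command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
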