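Package: cartipart
Title: Dual-Contrast Micro-CT Cartilage Partition Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies articular cartilage condition from dual contrast-enhanced
    micro-CT arthrography. Converts Hounsfield-unit attenuation volumes of
    osteochondral regions with a contrast-filled joint cavity into depth-resolved
    ioxaglate partition profiles and full-thickness volume-of-interest means,
    calibrated against separately scanned water and bismuth-nanoparticle phantoms.
    Includes automated articulating-surface and cartilage-bone interface detection,
    groove (surgical lesion) localisation, air-bubble quality control, matched
    Safranin-O digital-densitometry optical-density profiling with neutral-density
    filter calibration, nonparametric group comparisons with Bonferroni correction,
    and a seeded synthetic joint-phantom generator with full ground truth so every
    stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
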