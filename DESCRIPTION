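Package: rhozeff
Title: CBCT Tissue Segmentation via the Density-Effective-Atomic-Number Product
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kilovoltage cone-beam CT (CBCT) dosimetry in small-animal
    radiotherapy. Calibrates a monotonic third-degree polynomial between CBCT
    number and the product of mass density and effective atomic number
    (rho * Zeff), generates a database of artificial dose-equivalent tissues by
    constrained interpolation of ICRU reference tissue compositions, assigns a
    full material (density plus elemental composition) to every voxel of a CBCT
    volume, and exports Monte-Carlo-ready material and Hounsfield-range files.
    Includes the classic stoichiometric Hounsfield calibration, a 2D gamma-index
    dose comparison with isodose-masked difference statistics, and a synthetic
    digital-phantom generator for end-to-end validation without measured data.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
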