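Package: elemap
Title: Co-Registration of Elemental Imaging Maps with Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for spatial elemental imaging (LA-ICP-MS, XRF)
    alongside whole-slide histopathology. Reads per-element channel grids
    (iolite-style CSV/XLSX exports), consolidates them into multichannel
    elemental maps with first-class missing-data masks, and persists them in a
    chunked zarr-style store. Detects tissue via pseudo-log transform, masked
    Gaussian smoothing, Otsu or fixed thresholding and morphological cleanup.
    Estimates landmark-based rigid, similarity and affine transforms between
    the whole-slide-image frame and the elemental-map frame in physical
    micrometre coordinates, transfers QuPath GeoJSON / ASAP XML pathology
    annotations across modalities, rasterizes them to region label maps, and
    compares per-region elemental abundance with two-part hurdle-gamma
    regression (logistic detection part, log-link gamma abundance part,
    maximum-likelihood shape). Ships a seeded synthetic fixture generator with
    known ground truth and a command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    EBImage,
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
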