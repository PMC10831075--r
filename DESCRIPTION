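Package: maldistrain
Title: Strain-Level Typing of Bacteria from MALDI-TOF Mass Spectra
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating closely related bacterial strains from
    linear-mode MALDI-TOF mass spectra. Provides a seed-deterministic synthetic
    spectrum generator parameterised by per-strain peak intensity statistics,
    a preprocessing chain (quality control, cropping and resampling, Savitzky-Golay
    smoothing, top-hat morphological baseline subtraction, total-ion-count
    normalisation, ppm recalibration), peak picking on the total average spectrum,
    Anderson-Darling-gated ANOVA / Wilcoxon-Kruskal-Wallis discriminant peak
    selection with log2 fold changes and PCA, three classifier families
    (p-value-weighted quick classifier, prototype-based supervised neural network,
    genetic-algorithm KNN) with external validation metrics, and main-spectrum-profile
    (MSP) library construction with log-score identification and confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mzR,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
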