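Package: duodose
Title: Dual-Isotope SPECT Dosimetry for Holmium-166 Liver Radioembolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-level absorbed-dose assessment of the healthy liver for
    holmium-166 microsphere radioembolization using a simultaneous
    Ho-166/Tc-99m dual-isotope SPECT acquisition. Provides automatic
    healthy-liver segmentation by relative thresholding of the Tc-99m
    image (with spleen removal), local-deposition dose computation from
    Ho-166 counts, dose-volume-histogram metrics (mean dose, D70, V50),
    mask-agreement statistics (Sorensen-Dice, Hausdorff distance,
    Bland-Altman, paired tests), a dose-hepatotoxicity summary, and a
    synthetic SPECT phantom generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
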