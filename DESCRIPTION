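Package: wpbquant
Title: Simulation and Automated Quantification of Weibel-Palade Bodies in
    Endothelial Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for counting Weibel-Palade bodies (WPBs) in two-channel
    fluorescence z-stacks of endothelial cells. Provides a ground-truthed
    synthetic image generator (elliptical nuclei, rod-shaped WPBs, small round
    immature vesicles), a FIJI-macro-style segmentation pipeline
    (auto-contrast, 8-bit conversion, isodata/Otsu auto-thresholding,
    connected-component particle analysis with area and circularity filters),
    per-slide WPB/nuclei aggregation with confluency cohorting, and growth
    statistics (interval doubling times, growth-curve regression,
    slope-equality tests, one-way ANOVA, paired t-tests).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
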