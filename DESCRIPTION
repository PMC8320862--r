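Package: vascuseg
Title: Enhancement, Segmentation and Volumetry of the Embryonic Vasculature in 3D Light-Sheet Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the embryonic zebrafish vasculature in 3D
    light-sheet fluorescence microscopy stacks of transgenic endothelial
    reporter lines. Provides contrast-to-noise-ratio quality control,
    rigid motion correction of time-lapse series, two vascular enhancement
    paths (general median/rolling-ball filtering and Hessian-eigenvalue
    tubeness at a physical vessel scale), threshold-, cluster- and
    region-merging-based segmentation, ROI-restricted vascular volume
    quantification, and a synthetic vascular phantom generator with ground
    truth for validation, including membrane-labelled vessels with the
    characteristic cross-vessel double-peak intensity profile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
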