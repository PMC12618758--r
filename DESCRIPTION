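Package: dtistitch
Title: Stitching of Brain and Spinal Cord Diffusion MRI Fields of View
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fuses a brain diffusion-weighted MRI field of view with a
    cervical spinal-cord field of view into one continuous volume. The
    overlap is located by slice-wise cross-correlation against a reference
    slice, the in-plane rigid transform is refined over a small grid of
    rotation angles with an exhaustive integer translation search, and the
    two volumes are fused with linear feathering across the overlap.
    Downstream layers provide diffusion tensor fitting with fractional
    anisotropy maps, deterministic streamline tractography with
    fiber-length statistics, Dice-coefficient alignment QC on thresholded
    FA maps, and a deterministic synthetic two-field-of-view phantom
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
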