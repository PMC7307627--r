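Package: histotensor
Title: Structure-Tensor Histology, Automated Cell Counting and DTI-Histology
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative histology of stained brain sections and its
    correlation with diffusion-tensor MRI. Computes structure-tensor fields
    and an anisotropy index (AI) from myelin-stained photomicrographs;
    counts cells on Nissl-stained sections with a Chan-Vese preliminary
    segmentation, ellipse-fit triage and marker-based watershed correction
    of under-segmented components; derives FA, MD, AD, RD and Westin
    CL/CP/CS scalars from diffusion-tensor eigenvalues with a log-linear
    tensor fit; and reproduces the ROI-level statistics layer (unpaired
    t tests with Benjamini-Hochberg FDR, multiple regression of DTI on
    AI and cell density, and the chi projection). Synthetic generators for
    oriented fiber textures, Nissl-like cell images with ground truth,
    diffusion-weighted signals and sham/mTBI cohorts make the whole
    pipeline testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    jsonlite,
    png,
    RNifti,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
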