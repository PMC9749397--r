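Package: sbpet
Title: Personalized Synthetic-Baseline FDG-PET Synthesis and Abnormality Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes a healthy-appearing FDG-PET brain volume from a
    subject's own T1-weighted MRI with a two-stage (sketcher-refiner)
    conditional adversarial model, and quantifies metabolic abnormality as a
    personalized voxel-wise percent-deviation (Z%) map against that synthetic
    baseline. Includes a paired MRI/PET brain-phantom simulator with
    ground-truth tissue maps, atrophy and injectable hypometabolic lesions;
    the bespoke normalization and grid-standardization operators; patch-based
    volumetric inference with distance-weighted fusion; and synthesis-accuracy
    metrics (PSNR, RD%, Abs%, regional scores, joint-uptake linear fit).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
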