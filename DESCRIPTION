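Package: slipsir
Title: Slip Interface Recognition for MR Elastography of Tumor Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for slip interface imaging with brain MR elastography
    (MRE). Converts multi-offset, multi-direction encoded phase volumes to
    displacement fields, computes octahedral shear strain (OSS) and the
    amplitude-normalized NOSS map, and classifies each tumor-boundary point
    as adherent or non-adherent with the slip interface recognition (SIR)
    decision function, aggregating a tumor adhesion percentage over the 3D
    tumor surface. Includes a synthetic shear-wave phantom generator with
    known slip-surface ground truth, a boundary-normal NOSS-difference
    entropy baseline metric, and the evaluation statistics used to judge
    adhesion metrics (Cohen's kappa, Mann-Whitney AUC, DeLong's paired ROC
    test, two-way intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr, yaml, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
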