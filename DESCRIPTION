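Package: trabecula
Title: Trabecular Bone Histomorphometry, Micro-FE Stiffness and
    Cross-Modality Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trabecular bone micro-architecture from
    3D gray-scale volumes. Segments bone from clinical-resolution scans with
    an automated region-growing (ARG) scheme driven by homogeneity thresholds
    and from micro-CT-grade data with a histogram (Otsu) threshold; computes
    seven 3D histomorphometric structure parameters (BV/TV, Tb.Th, Tb.Sp,
    Tb.Sc, Tb.N, Tb.Nd, Tb.Tm) via topology-preserving skeletonization and
    sphere-fitting local thickness; estimates the apparent elastic stiffness
    tensor, Young's moduli E1-E3 and the minimum shear modulus by voxel-based
    hexahedral micro-FE homogenization under kinematic uniform boundary
    conditions; and predicts micro-FE stiffness from clinical-resolution
    structure parameters by Pearson correlation, simple and stepwise multiple
    linear regression, with Bland-Altman reproducibility analysis. Includes a
    synthetic phantom generator (thresholded anisotropic Gaussian random
    fields plus a scanner simulator) so the full study design can be
    exercised in silico.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
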