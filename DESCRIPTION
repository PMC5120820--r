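Package: pulse4d
Title: Quantification of Intracranial Aneurysm Pulsation from 4D CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cardiac-cycle volume pulsation of intracranial
    aneurysms from ECG-gated 4D CT angiography. Provides Hounsfield-unit
    threshold segmentation of the vascular lumen, per-phase sub-voxel
    isosurface modelling (3D+t surface model) with enclosed-volume
    computation, iterative-closest-point transfer of neck delineation points
    across cardiac phases, cut-surface separation of the aneurysm dome from
    its parent vessel, and per-phase aneurysm volume curves. Pulsation
    plausibility is assessed by comparing min-max normalized volume curves
    with an arterial pulse-wave template via the Hausdorff distance against a
    random-noise null distribution, and observer/modality agreement is
    summarised with Bland-Altman, intra-class correlation and Spearman
    statistics. A synthetic pulsating-aneurysm CT phantom generator with
    analytic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
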