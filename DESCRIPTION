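Package: respmotion
Title: Surrogate-Driven Respiratory Motion Modelling with MRI-Based
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds global respiratory motion models from
    respiratory-correlated 4D MRI: deformable image registration extracts a
    library of deformation vector fields (one per breathing phase bin) from an
    end-exhale reference, an image-based surrogate signal extracted from 2D
    cine-MRI drives phase interpolation and amplitude scaling of the library,
    and an inter-fraction baseline update compensates slow anatomical shifts.
    Ships a synthetic 4D abdominal breathing phantom with exact ground-truth
    deformations, and a validation suite covering registration error via 3D
    keypoint correspondences, 3D estimation error on points and tumour
    centre-of-mass, 2D cine landmark tracking metrics, and Jacobian-determinant
    plausibility of estimated deformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
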