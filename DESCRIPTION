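Package: DDHdx
Title: Clinical-Strategy Diagnosis of Developmental Dysplasia of the Hip on
    Pelvic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automatic measurement and rule-based diagnosis of
    developmental dysplasia of the hip (DDH) on anteroposterior pelvic
    radiographs of children. Annotated anatomical key points (lateral
    acetabular edge, top of the triradiate cartilage, inner and outer points
    of the proximal femoral metaphysis, bilaterally) are snapped onto the
    bony rim by local edge detection, the Hilgenreiner/Perkin/diagonal
    reference geometry is constructed, the acetabular index (AI) and lateral
    center-edge angle (LCEA) are measured, hips are graded on the IHDI
    scale, and a per-hip diagnosis (normal, other dislocation, or DDH with
    IHDI grade) is produced against nationality-, sex- and age-stratified
    normal AI criteria. A parametric pelvis-phantom generator with exact
    landmark ground truth and the study's agreement statistics
    (Bland-Altman, ICC, weighted kappa, DeLong) make the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    EBImage,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, ImageAnalysis
RoxygenNote: 7.3.3
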