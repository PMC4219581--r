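Package: posture3d
Title: Multi-Camera Photogrammetry and Agreement Statistics for Sitting
    Posture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A portable marker-based stereophotogrammetry pipeline for
    measuring three-dimensional sitting posture: direct linear
    transformation (DLT) calibration of a multi-camera rig from a fiducial
    calibration object, linear multi-view triangulation of reflective
    skin markers, derivation of anatomical landmarks and a subject-local
    coordinate system, and computation of nine named sagittal, frontal
    and transverse postural angles.  Includes the psychometric battery
    used to validate such instruments (Pearson correlation, Lin's
    concordance correlation, one-way random-effects intraclass
    correlation with variance components, and Bland-Altman limits of
    agreement), and a synthetic virtual-camera scene generator (rig,
    calibration object, mannequin, student postures, marker images and
    repeated-measures data) so the whole pipeline can be exercised and
    validated without physical hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
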