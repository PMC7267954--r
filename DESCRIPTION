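Package: conflicticc
Title: Test-Retest Reliability Analysis for Emotional-Conflict Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess test-retest reliability of task-based fMRI with an
    emotional conflict (face-word Stroop) paradigm. Generates counterbalanced
    trial sequences with conflict-adaptation coding, applies behavioral quality
    control and reaction-time filtering rules, fits first- and second-level
    general linear models on 4D BOLD series, and computes voxel-wise ICC(3,1)
    reliability maps with cluster- and atlas-level median summaries. A synthetic
    multi-site cohort generator with known variance components supports
    validation of every stage without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
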