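Package: kneebc
Title: Implant-Specific Knee Joint Simulator Boundary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to convert in vivo total knee arthroplasty (TKA) implant
    kinematics into force-controlled boundary conditions for six
    degree-of-freedom knee joint simulators, and to verify the resulting
    knee kinematics. Implements Grood-Suntay joint-coordinate-system
    decomposition, femoral condylar low-point extraction from implant
    meshes, rigid registration (Kabsch and iterative closest point),
    instrumented tibial tray calibration, activity-cycle waveform
    processing (time normalization, cohort averaging with implant-size and
    body-weight scaling, phase splitting), an iterative
    displacement-to-load profile tuning loop run against a quasi-static
    virtual knee surrogate, and one-dimensional statistical parametric
    mapping with random-field-theory thresholds. Seeded synthetic-data
    generators emulate the fluoroscopic, telemetric, and musculoskeletal
    inputs so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
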