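Package: porodyn
Title: Dynamic Finite-Element Modelling of Electric Currents in
    Electroporated Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-dependent finite-element simulation of the electric
    current flowing between needle electrodes during electroporation
    pulse trains.  Tissue conductivity follows a dynamic, field- and
    history-dependent law with three subsidiary state variables (level
    of poration, poration damage, thermal damage) and a capacitive
    current source with an RC time constant.  The quasi-static charge
    conservation equation is solved on tetrahedral meshes with Newton
    iteration and adaptive time stepping.  Includes a parametric
    two-needle-electrode mesh generator, Gmsh MSH import/export, VTK
    field export, oscilloscope-trace processing (down-sampling in
    groups and replicate averaging), inverse calibration of the
    saturated conductivity against measured current waveforms, and a
    seeded synthetic-trace generator for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
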