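Package: tmsfield
Title: Figure-8 TMS Coil Models and Induced Electric-Field Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how much geometric detail a figure-of-eight
    transcranial magnetic stimulation (TMS) coil model needs. Provides
    parametric generators for three coil models of increasing complexity
    (single outer loop per wing, in-plane spiral winding turns, stacked
    spiral layers), discretized Biot-Savart evaluation of the magnetic
    field B and vector potential A, a pulse model mapping stimulator
    settings to an equivalent DC current and maximum dI/dt, a quasi-static
    finite-element solve of the secondary electric field on labeled
    tetrahedral meshes, and an area-weighted normal-field activation
    metric on cortical surface patches. Includes synthetic fixtures
    (cylindrical phantom grids, concentric-sphere head meshes, gyrus-like
    surface patches, noisy pseudo-measured field maps) and the
    measurement-comparison operators used to validate coil models against
    field maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
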