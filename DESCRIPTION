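Package: rfasim
Title: Physics Simulation and Validation Toolkit for Hepatic Radiofrequency Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates radiofrequency ablation (RFA) with multi-tine umbrella
    electrodes driven by a recorded generator power trace. Couples a
    quasi-static electrical conduction solve (power-density deposition
    rescaled to the recorded power each control step) to a Pennes bioheat
    time march with perfusion, vessel heat-sink boundaries and an
    enthalpy-based evaporation model, and accumulates an Arrhenius thermal
    damage integral whose iso-surface is the simulated ablation volume.
    Includes the surrounding validation toolkit: parametric electrode and
    agar-phantom scene builders, tine detection in CT-like volumes, rigid
    pose estimation, region-based level-set segmentation of ablation
    boundaries in slice scans, equidistant boundary-point sampling,
    point-to-surface error reports, a manufacturer-chart half-ellipsoid
    comparator, and paired significance testing, plus synthetic fixture
    generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
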