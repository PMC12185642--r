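Package: avgflow
Title: Hemodynamic Descriptors and Lumped-Parameter Boundary Conditions for
    Arteriovenous Graft Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for patient-specific computational
    hemodynamics of arteriovenous grafts (AVGs). Provides a lumped-parameter
    (0D) vascular network model with quadratic resistances, inertances and
    three-element Windkessel outlets, including automated Windkessel
    calibration against a systolic pressure and an arterial flow-split target;
    volume descriptors of disturbed flow (turbulent kinetic energy, helicity
    descriptors h1-h4, local normalised helicity) on tetrahedral meshes; and
    near-wall shear descriptors (TAWSS, OSI, transverse WSS, topological shear
    variation index) on triangulated lumen surfaces, with area-weighted
    percentile thresholding, critical-area mapping per region of interest and
    Dice similarity reporting. Ships analytic fixtures (Womersley and helical
    flows, prescribed wall-shear patterns, a toy AVG network) so every
    computation can be validated against closed forms without solver output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
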