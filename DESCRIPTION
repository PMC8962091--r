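Package: tcpcflow
Title: 4D Flow CMR Energetics of the Total Cavopulmonary Connection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies blood-flow energetics in the Fontan total
    cavopulmonary connection (TCPC) from 4D phase-contrast velocity
    fields: voxel-wise kinetic energy and viscous energy loss rate from
    the Navier-Stokes dissipation function, velocity anti-aliasing,
    semi-automatic lumen segmentation on magnitude-weighted speed images,
    centerline extraction with five-segment labeling, cross-sectional
    area profiles and through-plane flows, and flow and length
    normalization. Ships synthetic pulsatile laminar phantoms with
    analytic ground truth and a synthetic patient cohort generator, plus
    the cohort statistics layer (normality-driven descriptives,
    correlation analysis with strength labels, Kruskal-Wallis segment
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    MASS,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
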