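Package: magsense
Title: Semi-Analytical Simulation of a Magnetofluidic Capacitive Sweat Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale multiphysics model of a microfluidic immunosensor that
    concentrates antibody-functionalized magnetic nanoparticles (MNPs) with
    planar spiral microcoils and reads their occupancy out capacitively.
    Implements the magnetostatic field of spiral microcoils by elliptic-integral
    Biot-Savart superposition, the fully developed laminar velocity field of a
    rectangular microchannel, overdamped Lagrangian transport of MNPs under
    magnetophoretic force and Stokes drag with a wall-trapping criterion, and a
    layered-dielectric (PDMS-channel-PDMS) capacitance model with an
    MNP-occupancy sensitivity analysis.  Includes seeded scenario generators,
    parameter-sweep experiment drivers and a reproducibility report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    yaml,
    deSolve,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
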