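Package: cryolayer
Title: Particle Z-Height, Interface-Adsorption and Orientation Analysis for
    Cryo-EM Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the spatial distribution of macromolecular particles
    inside vitreous ice from single-particle cryo-EM metadata. Converts
    per-particle refined defocus values to z-heights, fits least-squares
    planes per micrograph, summarises signed orthogonal distances with
    kernel density estimates, moment-coefficient skewness tiers, layering
    (unimodal/bimodal) calls and a central-extent ice-thickness estimate,
    and builds point-group symmetry-reduced (rot, tilt) orientation
    heatmaps. A companion tomogram module fits particle and interface
    (air-water, graphene-water) planes from 3D coordinates and measures
    particle-to-interface spacings. A synthetic-data generator emulates
    mid-ice, interface-adsorbed, bimodal and double-layer placement models
    with known ground truth so that every stage is testable without any
    cryo-EM dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
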