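Package: atriasim
Title: Multiscale Simulation of Human Atrial Electrophysiology and
    Atrial-Fibrillation Remodelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating human atrial electrophysiology across
    scales: an updated Courtemanche-family atrial myocyte model with
    Nygren/Maleckar-style outward potassium currents and a two-compartment
    sarcoplasmic-reticulum calcium handling system; a family of regional
    cell-model variants (crista terminalis, pectinate muscle, appendages,
    septum, Bachmann's bundle, left atrium, pulmonary veins); four
    scenarios of atrial-fibrillation-induced electrical remodelling applied
    as parameter transforms; a monodomain reaction-diffusion tissue solver
    on voxel geometries with fibre anisotropy; and the analysis protocols
    used to characterise arrhythmogenic substrates (action-potential
    duration and restitution, effective refractory period, S1-S2
    vulnerability windows for unidirectional block and re-entry, conduction
    velocity, and dominant-frequency mapping).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
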