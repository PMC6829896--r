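Package: fpphotocycle
Title: Photocycle Kinetics and Photophysics of GFP-Family Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the photocycle of GFP-like fluorescent
    proteins from molecular-simulation and spectroscopy-style inputs:
    chromophore torsion and hydrogen-bond censuses on coordinate
    trajectories, censored first-passage kinetics of excited-state
    chromophore twisting, radiative lifetimes from excitation energies and
    oscillator strengths, a kinetic model of the photocycle (apparent
    lifetime, fluorescence quantum yield, bleaching yield, relative
    photostability), cosine-series torsional-potential fitting, analysis of
    photobleaching, photoconversion ("redding") and time-correlated
    single-photon-counting decay curves, and synthetic-data generators with
    bookkept ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
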