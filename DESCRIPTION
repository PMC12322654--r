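Package: azoswitch
Title: Thermokinetics, Ensemble Spectra, and Photoswitching Kinetics of
    Azobenzene Photoswitches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterisation toolkit for red-shifted azobenzene
    photoswitches. Converts measured thermal cis->trans relaxation
    half-lives into Eyring activation free energies and back, and
    extrapolates half-lives across temperatures; assembles broadened
    UV-vis spectra from nuclear ensembles of vertical excitation
    energies and calibrates a systematic energy shift against measured
    spectra; extracts N=N and C-N dihedral angles from multi-frame XYZ
    trajectories and correlates their cosine transforms with
    photo-properties; models two-state photoisomerisation kinetics
    (photostationary states, quantum-yield estimation anchored by NMR
    isomer ratios, mono- and bi-exponential relaxation and degradation
    fits). A seeded synthetic-data generator emulates conformer
    ensembles, spectra, and kinetic traces with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
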