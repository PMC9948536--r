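Package: memlayer
Title: Structural and Thermodynamic Analysis of Phospholipid Monolayers and
    Supported Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for model-membrane experiments on Langmuir
    monolayers and electrode-supported bilayers: surface pressure-area
    isotherm mechanics and mixing thermodynamics (compressibility modulus,
    excess area, excess and total Gibbs energy of mixing); reduction of
    chronocoulometric current transients to absolute charge density curves,
    interfacial capacitance and bilayer film pressure; pseudo-Voigt band
    decomposition of polarization-modulated infrared reflection absorption
    spectra with ester-carbonyl solvation fractions and hydrocarbon chain
    tilt from transition-dipole intensity ratios; grazing-incidence X-ray
    diffraction peak fitting and two-dimensional unit-cell indexing; and
    slab-model specular reflectometry (Abeles matrix and Parratt recursion
    with Nevot-Croce roughness and Gaussian resolution smearing) with
    multi-contrast co-fitting and headgroup solvation/water-per-lipid
    calculations. A synthetic-data module generates ground-truth-known
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
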