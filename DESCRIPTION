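Package: isovib
Title: Isotope-Edited Infrared Difference Spectroscopy and Harmonic Mode Analysis
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for isotope-edited Fourier-transform infrared (FTIR)
    difference spectroscopy of proteins and for the vibrational analysis that
    assigns the observed bands. Builds double-difference spectra from paired
    unlabelled and 15N-labelled light-minus-dark difference spectra using
    unbiased least-squares scaling, deconvolves them with a constrained
    sum-of-Lorentzians band model fitted by Levenberg-Marquardt least squares
    with exact constraint reparameterization, and assigns bands by harmonic
    vibrational analysis of Cartesian Hessians: isotope mass substitution,
    Eckart projection, normal-mode pairing across isotopomers, infrared
    intensities from dipole derivatives, Wilson B-matrix construction and
    potential energy distribution (PED) decomposition over automatically
    generated internal coordinates. Includes stick-spectrum convolution to
    simulated IR and UV-vis spectra and seeded generators for synthetic
    experimental pairs and toy valence-force-field molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
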