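Package: mesoclust
Title: Detection and Quantification of Mesoscale Clusters in Sub-Saturated
    Protein Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying mesoscale clustering of phase-
    separating proteins in sub-saturated solutions. Implements autocorrelation
    estimators (direct and multi-tau) for intensity traces and photon streams;
    dynamic light scattering fits (single- and two-exponential, Stokes-Einstein
    sizing, regularized size-distribution inversion, slow-mode detection);
    nanoparticle tracking analysis (trajectory linking, per-particle diffusion,
    size/concentration and volume-fraction estimates); single-molecule burst
    selection with maximum-likelihood fluorescence lifetimes and FRET
    efficiency/stoichiometry with static and dynamic FRET lines; fluorescence
    correlation spectroscopy fits with two 3D-Gaussian diffusion components and
    a kinetic relaxation term; microfluidic confocal spectroscopy cluster
    counting, flux and concentration; preferential interaction coefficients and
    site-site radial distribution functions from solvation trajectories; and
    saturation-concentration estimation from spin-down assays. Ships synthetic
    generators (Brownian suspensions, photon streams, scan traces, solvation
    boxes, spin-down series) that emulate the statistical structure of the
    corresponding instrument records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bursts.R'
    'constants.R'
    'correlate.R'
    'dls.R'
    'fcs.R'
    'io.R'
    'mcs.R'
    'mesoclust-package.R'
    'nta.R'
    'prefint.R'
    'syndata-photons.R'
    'syndata-scan.R'
    'syndata-solvation.R'
    'syndata-suspension.R'
    'thermo.R'
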