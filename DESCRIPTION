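Package: fccsfret
Title: Ligand-Receptor Binding Affinity from Two-Colour FCCS and FLIM-FRET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative inference of ligand-receptor complex integrity from
    fluorescence fluctuation data. Implements two-colour fluorescence
    cross-correlation spectroscopy (FCCS) analysis end to end: reference-dye
    calibration of confocal detection volumes, multi-tau auto- and
    cross-correlation of binned photon traces, triplet-diffusion and
    pure-diffusion model fitting, and conversion of fitted amplitudes into
    concentrations and equilibrium dissociation constants with exclusion and
    lower-bound rules. Also fits TCSPC lifetime decays by Poisson maximum
    likelihood and converts donor quenching into FRET efficiencies and
    donor-acceptor distances via the Forster relation, and provides the
    accompanying morphometric quantifications (filopodium classification,
    circularity, domain ratios, kinase-translocation-reporter activity
    profiles). A Brownian-dynamics photon-trace simulator with known ground
    truth validates every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
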