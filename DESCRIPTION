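Package: tg43seed
Title: TG-43U1 Dosimetry Analysis for Low-Energy Brachytherapy Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the AAPM TG-43U1 dose-calculation formalism for
    low-energy interstitial brachytherapy seeds: point- and line-source
    geometry functions, extraction of the radial dose function g(r) and the
    2D anisotropy function F(r,theta) from polar dose-rate grids, air-kerma
    strength estimation from vacuum ring-kerma profiles, dose-rate constants
    and their experimental/Monte Carlo consensus averaging, polynomial
    modelling of g(r), and forward dose-rate reconstruction. Includes the
    full thermoluminescent dosimeter (TLD) reading-reduction chain
    (background subtraction, per-chip sensitivity normalisation, calibration,
    decay-corrected effective exposure time, quadrature uncertainty
    combination) and a synthetic generator of Monte-Carlo-like dose grids,
    ring-kerma profiles and TLD experiments with known analytic ground truth.
    Ships a consensus dosimetry dataset for a Pd-103 seed as packaged
    plain-text fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
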