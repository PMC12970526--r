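Package: guvchol
Title: Quantifying Cholesterol Incorporation in Giant Unilamellar Vesicle
    Membranes from Spectral GP and FLIM Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying cholesterol content in the
    membranes of giant unilamellar vesicles (GUVs) from two complementary
    fluorescence readouts: generalized polarization (GP) of the solvatochromic
    probe NR12A computed from confocal spectral image stacks, and
    intensity-weighted fluorescence lifetimes of the mechanosensitive probe
    Flipper-TR obtained by biexponential reconvolution fitting of TCSPC
    decays, with phasor-plot analysis for phase-separated membranes. Probe
    readouts are converted to mol% cholesterol by inverting a weighted linear
    calibration fitted to reference vesicles of known composition, with full
    first-order error propagation. A synthetic phantom generator emulates
    equatorial GUV ring images with photoselection modulation and Poisson
    counting noise, and TCSPC decay histograms with a finite instrument
    response, so that every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
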