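Package: ldctsim
Title: Low-Dose CT Simulation by Projection-Domain Noise Insertion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates reduced-dose computed tomography scans by inserting
    properly scaled quantum (Poisson) and electronic (Gaussian) noise into
    projection data, with an automated water-phantom calibration loop.
    Includes digital phantoms (20-cm water cylinder, head phantom with
    contrast-filled tubes), a parallel-beam scanner model with a
    Poisson-Gaussian measurement chain, filtered backprojection
    reconstruction, region-of-interest noise and signal-to-noise analysis,
    score-ledger bookkeeping for reader studies, and the exact sign test,
    Mann-Whitney U test and Cohen's kappa used to compare true and
    simulated dose series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
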