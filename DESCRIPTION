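Package: phosdyn
Title: Protein Dynamics from Oxygen-Quenched Phosphorescence Lifetimes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for time-resolved phosphorescence quenching
    studies of protein conformational dynamics. Fits photon-counting decay
    traces with sums of discrete exponentials, computes the intensity-weighted
    ensemble-average lifetime, normalizes temperature series by the
    frozen-state reference lifetime, and fits a two-state (frozen/molten)
    thermodynamic activation model to the resulting transition, with
    covariance- or bootstrap-based parameter uncertainties. Includes a
    synthetic-data generator with Poisson photon-counting noise that emulates
    the experimental acquisition, so the full pipeline is testable against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
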