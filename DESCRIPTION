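Package: rhoquench
Title: Dual-Readout Analysis of CFTR Membrane Proximity and Channel Function
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@rhoquench.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for a dual-colour, image-based fluorescence assay
    that simultaneously quantifies how much CFTR protein sits at or near the
    plasma membrane and how well it conducts anions. From mCherry/YFP microscopy
    image pairs it segments adherent cells (watershed on a distance transform),
    extracts a membrane-proximal band and computes the per-cell membrane-proximity
    metric rho (band YFP over whole-cell mCherry, plate-normalised to wild-type
    wells). From halide-sensitive YFP quench time series it estimates the maximal
    iodide-entry rate and, by fitting a single-compartment conductance model with
    a Goldman-Hodgkin-Katz flux law, the steady-state CFTR conductance. Plate-level
    paired statistics, Hill dose-response fits and linear interpolation utilities,
    together with a fully ground-truthed synthetic data generator, complete the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
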