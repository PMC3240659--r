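Package: steadyloop
Title: Loop-Design Microarray Analysis of Transcriptomic Steady States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for detecting transcriptomic steady-state
    responses to repeated small perturbations measured on two-color cDNA
    microarrays in a loop design. Provides spot-level quality filtering
    (signal-to-noise, spot diameter, pixel coefficient of variation),
    within-print-tip-group intensity-dependent normalization, least-squares
    estimation of per-gene time-course contrasts from the loop design with
    detection of non-estimable (singular) genes, and a template-correlation
    statistic that scores each expression profile against the ideal
    perturbation-then-relaxation pattern, calibrated against a simulated and
    an analytic null distribution. A synthetic spot-level data generator with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
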