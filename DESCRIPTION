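Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selection of stable reference (housekeeping) genes for RT-qPCR
    relative quantification. Provides quantification-cycle (Cq) preprocessing
    (technical-replicate collapsing, plate-control quality checks,
    standard-curve amplification-efficiency estimation and
    efficiency-corrected Cq transformation), four expression-stability
    algorithms (geNorm M value with pairwise variation V, NormFinder
    model-based stability, BestKeeper dispersion, and the comparative
    delta-Ct method), and a comprehensive ranking by the geometric mean of
    per-algorithm ranks. Includes a synthetic qPCR data generator with known
    ground truth, and published stability tables from a beluga whale blood
    reference-gene study as packaged example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
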