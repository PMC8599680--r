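Package: opmvef
Title: Temporal Resolution Analysis of Visually Evoked Magnetic Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for stimulus-locked visually evoked fields
    (VEFs) recorded with optically-pumped (OPM) or SQUID magnetometers:
    zero-phase band-pass/band-stop filtering, epoching with trial
    rejection, trial averaging with per-timepoint standard-error bands,
    peak characterization by adjacent local minima (width w, amplitude A),
    the temporal-resolution figure of merit eta = sqrt(A)/w with
    first-order uncertainty propagation, exact and Taylor-expanded
    resolution limits, inter-site (POz to Oz) component delay estimation
    with propagated uncertainties, dual-axis planar field magnitudes, and
    run/participant reproducibility via Pearson correlation. Includes a
    synthetic two-site, dual-axis magnetometer simulator (flash and
    pattern-reversal stimulus schedules, Gaussian evoked components,
    sensor noise, 50 Hz line interference, stand-off amplitude scaling)
    so the full pipeline is testable without participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    data.table,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
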