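Package: prmassay
Title: Scheduled Parallel-Reaction-Monitoring Assay Construction for
    Nominal-Mass Instruments
Version: 0.1.0
Authors@R:
    person("prmassay", "maintainers", email = "prmassay@example.org",
           role = c("aut", "cre"))
Description: Builds scheduled parallel-reaction-monitoring (PRM) assays
    from global DDA spectrum libraries or DIA chromatogram libraries for
    quadrupole-linear-ion-trap instruments. Ranks peptides by library
    signal (precursor intensity for DDA, third-largest fragment intensity
    for DIA), selects diagnostic transitions, aligns library retention
    times to current column conditions with a robust affine fit, and
    packs targets into retention-time windows with a greedy algorithm
    under a hard per-cycle assay-density cap and per-protein peptide
    caps. Includes cycle-time/injection-time budget arithmetic, dimethyl
    matched-matrix background-exclusion validation, matrix-matched
    calibration-curve figures of merit (bilinear-fit LoD, bootstrap-CV
    LoQ), seeded synthetic-data generators with known ground truth, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
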