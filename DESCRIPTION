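Package: ifxdyn
Title: Simulation of TNF-alpha Dynamics Under Infliximab Therapy in
    Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state receptor-ligand-antibody model of tumor necrosis
    factor-alpha (TNF-alpha) kinetics under infliximab infusion therapy, with
    dynamic TNF-alpha production calibrated to the drug-free steady state.
    Provides closed-form drug-free equilibria, stiff event-aware integration
    of infusion schedules, per-cycle peak/trough extraction, clearance-rate
    sweeps, an inverted Hill model linking trough drug exposure to clearance,
    and an adaptive dosing loop in the style of therapeutic drug monitoring,
    including dose-count tables and a dose-recommendation strategy for
    Crohn's disease and ulcerative colitis presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
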