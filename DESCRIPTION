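Package: resusim
Title: Guidance Engine, Scenario Simulator and Scoring Toolkit for
    Pediatric Cardiac Arrest Resuscitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, deterministic guidance engine for pediatric
    advanced life support (PALS) style cardiac-arrest management: a
    declarative flow graph of guidance screens, countdown timers with
    priority semantics, weight-based dose and defibrillation-energy
    calculation, and an append-only event log. Around the engine it
    provides a scripted-agent discrete-event simulator that produces
    synthetic team event logs for control and intervention study arms,
    deviation-checklist (16-item) and clinical-performance (0-13)
    scoring of those logs, time-to-epinephrine measurement, User
    Experience Questionnaire and NASA Raw Task Load Index scoring with
    Cronbach's alpha, and small-sample group comparisons (exact
    Mann-Whitney and Fisher tests) formatted as study-style report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
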