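Package: birdsearch
Title: Simulation and Analysis of an Adaptive Visual Search Task for
    Hemispatial Neglect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for an immersive
    visual search task with between-round adaptive difficulty scaling.
    Implements the 15-level difficulty table and level-switching rule, an
    event-based model of the search game driven by synthetic player agents
    (healthy, elderly, and agents with a lateralized attentional bias
    emulating left hemispatial neglect), the Center of Cancellation
    statistic for cancellation sheets, lateralized search-time measures,
    level-trajectory and plateau analysis, hand-trace summaries,
    questionnaire scoring, and reproducible session logging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
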