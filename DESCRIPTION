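Package: dynamotype
Title: Bifurcation Maps and Bursting Classes of the Epileptor Seizure Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and bifurcation analysis of the Epileptor
    phenomenological seizure model and of a minimal bursting model built on a
    layer of the degenerate Takens-Bogdanov unfolding. Provides closed-form
    saddle-node and Andronov-Hopf bifurcation curves of the Epileptor's fast
    subsystem with all eight fast parameters explicit, simulation-based
    amplitude/frequency maps over the slowly driven parameter plane,
    numerical inference of the saddle-homoclinic curve from frequency scaling,
    projection of full-model trajectories onto the map, and classification of
    bursters by their seizure onset/offset bifurcation pair (dynamotype):
    SN/SupH, SN/SH, SN/SN, SupH/SH and SupH/SupH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
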