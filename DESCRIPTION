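Package: pwosim
Title: Agent-Based Simulation of Private Woodland Owner Timber Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time agent-based model of timber-harvesting decisions
    by private woodland owners on a grid of forest parcels. Each owner makes an
    annual harvest decision from a logistic pre-disposition updated by visits
    from professional foresters and conservation-trained peer leaders and by
    opinion spread among neighbouring and randomly met owners, with trust in
    each influencer type acting as the probabilistic gate on influence and
    hardening into permanent belief after sustained highs or lows. Includes the
    batch-experiment machinery for one-variable parameter sweeps with
    replicates, pooled summaries, and one-way ANOVA across levels, plus CSV
    output and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
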