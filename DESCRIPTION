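Package: nh3trade
Title: Trade-Embodied Agricultural Ammonia Emissions, PM2.5 Health Burdens,
    and Mitigation Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiregional input-output (MRIO) accounting of agricultural
    ammonia (NH3) emissions embodied in international trade, a linear
    source-receptor surrogate for the atmospheric contribution of NH3 to
    fine particulate matter (PM2.5), integrated exposure-response (IER)
    attribution of premature mortality with Monte-Carlo uncertainty, a
    bilateral health-effect trade network with community detection and
    centrality statistics, and NH3 mitigation scenarios (two
    trade-reallocation linear programs plus production- and
    consumption-side technology scenarios). A seeded synthetic world
    generator emulates the statistical structure of the required inputs
    (balanced multi-region economy, heavy-tailed trade network, smooth
    concentration fields, log-normal inventory uncertainty) so the whole
    chain is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
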