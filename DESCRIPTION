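Package: pggevol
Title: Evolution of Selfish Risk-Seeking and Generous Risk-Averse Agents in
    a Public Goods Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of a community of selfish risk-seeking
    and generous risk-averse agents that harvest a shared, finite resource,
    play a public goods game, and reproduce in proportion to fitness through
    a heritable, mutating parent-to-offspring phenotype-transmission
    mechanism, over thousands of non-overlapping generations. Provides
    seed-reproducible single realizations and ensembles, equilibrium and
    extinction summaries, parameter sweeps over mortality rate, community
    cost and environmental offer, model variants (conditional cooperation,
    individual cost for selfish agents, perfect transmission, no mutation),
    trajectory CSV/JSON input and output, and a thin command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
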