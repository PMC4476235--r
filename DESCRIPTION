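Package: pathdose
Title: Pathway-Network Modeling of Dose-Response and Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts dose-response curves and two-drug combination effects
    (synergism or antagonism) for inhibitors acting on a signaling pathway.
    A directed pathway network with a designated exit node is perturbed by
    converting inhibitor doses and binding constants into fractions of
    target inhibition under non-competitive Michaelis-Menten kinetics;
    inhibition inflates the resistance of edges leaving each target, and the
    drug effect is read out from weighted shortest-path connectivity
    measures: network efficiency, network flux, and their geometric-mean
    combination. Includes Hill-type curve fitting, Chou-Talalay combination
    index and isobologram analysis, a transcription of the LPS-induced PGE2
    production network, and generators for synthetic pathways and binding
    affinity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
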