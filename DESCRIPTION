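Package: peerspread
Title: Simulated Social Network Interventions for Physical Activity in School Classes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted sociometric networks of school classes from peer
    nomination records, runs a deterministic three-phase agent-based model of
    physical-activity diffusion (weighted peer influence, a socio-environmental
    anchor derived from family affluence, and a threshold gate), simulates five
    influence-agent selection conditions (in-degree, betweenness and closeness
    centrality, random agents, and a no-intervention control), and evaluates the
    resulting class-level success rates with planned Helmert contrasts in linear
    mixed-effects models (Satterthwaite degrees of freedom), a sphericity-corrected
    repeated-measures ANOVA, and moderation by network density and Freeman
    centralization. Includes a synthetic cohort generator that emulates the
    statistical structure of a 26-class sociometric sample.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    lme4,
    numDeriv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
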