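Package: callnet
Title: Caller Identity, Social Networks and Playback Responses in Primate Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational chain of primate playback experiments
    on third-party social knowledge: extraction of acoustic features from
    conflict vocalisations and assembly of two-caller conflict stimuli;
    permuted discriminant function analysis (pDFA) of caller identity with a
    permutation null that respects the nesting of call units within calling
    bouts; quantification of social relationships from proximity scans,
    grooming and agonistic interactions (dyadic friendship scores, Elo
    ratings, maternal kinship, eigenvector centrality, Mantel matrix
    correlation and split-half network stability tests); rule-based selection
    of caller dyads for six playback conditions; and Gaussian linear and
    mixed models of post-playback looking time with likelihood-ratio tests
    and collinearity and residual diagnostics. A synthetic-data module
    generates every input stream with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    signal,
    igraph,
    lme4,
    lmerTest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    car,
    withr
Config/testthat/edition: 3
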