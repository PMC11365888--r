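Package: ethofield
Title: Open-Field Behavioral Phenotyping from Frame-Wise Movement Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of spontaneous open-field behavior in mice
    from per-frame movement labels and back-keypoint trajectories: kinematic
    label correction, time budgets and temporal dynamics of 13 movements and
    5 behavioral clusters, data-driven center/perimeter arena zoning from
    occupancy growth curves, cluster transition networks with betweenness
    centrality, and linear discriminant genotype classification. Includes a
    semi-Markov synthetic cohort generator emulating genotype-by-sex
    differences in dwell times, transition structure, locomotion and
    thigmotaxis, so the full pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
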