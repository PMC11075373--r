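Package: narcscreen
Title: Network-Based Screening for Overprescription of Medical Narcotics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for national-scale prescription monitoring of
    medical narcotics (appetite suppressants, zolpidem, propofol). Filters
    dispensing records against safe-use limits (daily dose, episode duration,
    cumulative duration, prescribing frequency), builds the undirected
    two-mode hospital-patient prescription network and its one-mode hospital
    projection, computes the standard network-metric suite (degree, weighted
    degree, betweenness, eigenvector centrality, Louvain communities, path
    statistics), and derives screening statistics: top-k% degree/weighted-degree
    overlap, the Narcotics Safety Index (mean prescriptions per connected
    patient), prescription-pattern quadrants, and hospital size/region
    stratification. Includes a seeded synthetic prescription-data generator
    emulating restricted national reporting data, with per-drug presets
    reproducing the qualitative cross-drug network contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
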