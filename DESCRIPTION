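Package: parascreen
Title: Host-Parasitoid Association Screening in Protist Metabarcoding Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting candidate host-parasitoid associations in
    18S rRNA metabarcoding time series of marine plankton. Provides readers
    and writers for OTU count tables, ranked (PR2-style) taxonomies, trophic
    rule tables and environmental records; abundance-based sample and OTU
    filtering; literature-rule trophic annotation; peak and bloom detection
    on irregularly sampled relative-abundance series; classification of
    candidate pairs into lagged (Lotka-Volterra-like) and simultaneous
    co-occurrence signatures with lag estimation; canonical correspondence
    analysis with permutation significance tests and significance-then-AIC
    forward selection of environmental constraints; and a synthetic
    community generator with planted host-parasitoid dynamics and ground
    truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
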