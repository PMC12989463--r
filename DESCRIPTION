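Package: diatomtraits
Title: Trait-Based Diatom Metrics, TITAN Changepoints and Phosphorus
    Benchmarks for Periphyton Bioassessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for developing and evaluating trait-based diatom
    metrics along a periphyton-mat phosphorus gradient.  Assigns low-P
    and high-P traits to taxa by gradient regression, by threshold
    indicator taxa analysis (TITAN) with permutation z-scores and
    bootstrap purity/reliability, or from user-supplied literature
    lookups; computes four trait-metric calculation types per sample
    (proportion of valves, proportion of taxa, number of taxa, and
    relative log-abundance weighting) together with diversity metrics
    and weighted-average inferred phosphorus; scores metric performance
    against the stressor and a geographic disturbance gradient; and
    derives candidate management benchmarks from regression-tree
    changepoints, cluster-group phosphorus percentiles, and TITAN
    community sum(z) profiles.  A seeded synthetic assemblage simulator
    with Gaussian species responses and fixed-effort multinomial counts
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
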