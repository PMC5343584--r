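Package: kelpcast
Title: Niche Modelling and Dispersal-Latency Range Reconstruction for
    Coastal Species
Version: 0.1.0
Authors@R: person("Range Edge", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples ecological niche modelling (monotonically constrained
    boosted regression trees over weakly correlated predictor subsets,
    selected by the Minimum Predicted Area transferability criterion) with a
    dispersal-distance / latency-period occupancy automaton to hindcast and
    forecast the range edge of coastal species such as annual kelps. Includes
    seasonal extreme-event predictor derivation (consecutive days above
    temperature and wave thresholds, Bakun coastal upwelling index from wind
    stress), Mahalanobis + K-means pseudo-absence generation, True Skill
    Statistic evaluation, and a synthetic coastal-world generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
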