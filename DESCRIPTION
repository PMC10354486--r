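Package: kitepeck
Title: Dynamic Sibling-Aggression Networks and Food Allocation in
    Asynchronously Hatching Broods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse directed aggression (pecking) networks and
    parental food allocation in broods of three asynchronously hatching
    nestlings. Implements a permutation-based null model for daily directed
    interaction frequencies ("tendency to peck"), bootstrap uncertainty for
    smooth regressions of that tendency on sibling age difference, daily
    delivered biomass and post-hatching phase, classification of aggression
    patterns (close competitor, downward heuristic, bullying), a multinomial
    additive model of feeding-bout allocation among senior, middle and junior
    nestlings, and a synthetic-brood generator that emulates the statistical
    structure of nest-camera event logs so every pipeline stage can be tested
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
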