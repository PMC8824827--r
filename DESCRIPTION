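Package: beereml
Title: Variance Component Estimation for Honeybee Colony Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of honeybee breeding populations with
    separate queen (maternal) and worker-group (direct) genetic effects,
    construction of the honeybee-specific additive relationship matrix over
    queens, worker groups and mating stations (with sparse inverse), and
    restricted maximum likelihood estimation of variance components under
    the colony, queen and worker models via EM-REML and AI-REML. Includes
    the projected-variance theory linking the simplified queen and worker
    models to the full colony model, plausibility filtering of estimation
    runs, and bias/standard-error evaluation across simulated designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, jsonlite, methods, stats, utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
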