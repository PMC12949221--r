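Package: pollevol
Title: Eco-Evolutionary Dynamics of Plant-Pollinator Trait Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of a two-plant, two-pollinator community
    in which Lotka-Volterra competition is coupled to Gaussian trait-matching
    mutualism, and pollinator traits evolve by adaptive dynamics (invasion
    fitness, analytic selection gradients, gradient-ascent trait substitution)
    to an evolutionarily stable state. Provides equilibrium solvers, fitness
    landscapes, diversity metrics (scaled Gini-Simpson index and Rao's
    quadratic entropy), and orchestration of carrying-capacity sweeps that
    quantify how plant-abundance change propagates to pollinator abundance,
    species evenness and functional diversity on ecological and evolutionary
    timescales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
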