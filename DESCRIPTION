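Package: tomcg
Title: Evolutionary Dynamics of Theory-of-Mind Strategies in Centipede Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of recursive Theory-of-Mind strategies in
    finite populations playing centipede games. Strategies are (t, k) duples
    combining a prior take-threshold belief with a level-k recursive reasoning
    depth; three stochastic reasoning processes (unconditional, payoff
    conditional, and payoff conditional with reasoning inertia) turn beliefs
    into noisy take decisions via a cognitive-error branching process.
    Provides exact threshold and action distributions, pairwise expected
    payoffs (analytic and Monte Carlo), fixation probabilities under the
    Fermi pairwise-comparison rule, the rare-mutation embedded Markov chain
    with its stationary distribution and marginals, gradients of selection,
    evolutionary-robustness reports, an agent-based mutation-selection
    simulator, and grid-search calibration of selection strength and error
    rate against empirical game-ending-step distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
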