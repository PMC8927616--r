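Package: qrepd
Title: Quantal Response and Nash Equilibria for the Prisoner's Dilemma in
    Memory-One Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers and estimators for the iterated Prisoner's Dilemma played
    in memory-one (Markov) strategies, parameterized by the tolerance to
    defection (the probability of cooperating after the opponent defected) and
    mutual cooperation (the probability of cooperating after the opponent
    cooperated).  Computes stationary cooperation probabilities and expected
    payoffs of the coupled response dynamics, the symmetric totally mixed Nash
    equilibrium curve derived from first-order conditions, and the symmetric
    logit quantal response equilibrium (QRE) traced over the rationality
    parameter by deterministic multistart minimization of the fixed-point
    residual.  Includes landmark extraction from the traced QRE curve
    (intersection with the Nash curve, defection-collapse onset, phase-boundary
    classification), transition-count estimation of Markov strategies from
    round-by-round play logs, and a synthetic experiment generator emulating a
    two-phase socialization design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
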