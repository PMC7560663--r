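Package: memone
Title: Best Response Memory-One Strategies in the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying memory-one strategies in the Iterated
    Prisoner's Dilemma with full knowledge ("theory of mind") of a set of
    memory-one opponents. Computes exact long-run utilities both from the
    underlying four-state Markov chain and from a closed-form ratio of
    quadratic forms in the player's cooperation probabilities; constructs
    best-response memory-one strategies by enumerating the discrete candidate
    set of stationary points on every face of the unit 4-cube, or by seeded
    Bayesian optimisation; measures how far a strategy is from the nearest
    zero-determinant (extortionate) strategy via a least-squares projection
    (SSE); evaluates dynamically re-optimising best-response players in Moran
    processes via exact birth-death fixation probabilities; and trains and
    simulates a 17-parameter lookup-table strategy ("Gambler") to probe the
    limits of one-round memory. Includes seeded experiment harnesses
    reproducing the tournament, Moran and longer-memory studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
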