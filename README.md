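# memone

Best-response memory-one strategies in the Iterated Prisoner's Dilemma
(IPD), for researchers in evolutionary game theory who want exact long-run
utilities, provably complete best-response searches, and reproducible
experiments on the limits of extortionate and short-memory play.

## The model

A memory-one strategy is a vector `p = (p1, p2, p3, p4) ∈ [0,1]^4` of
cooperation probabilities conditioned on the previous round's outcome
(CC, CD, DC, DD, from the focal player's perspective). Against a memory-one
opponent `q`, play is a 4-state Markov chain with stationary vector `v`, and
the long-run payoff per round is `u_q(p) = v · (R, S, T, P)` with the usual
payoffs `T > R > P > S`, `2R > T + S` (default `(R, P, S, T) = (3, 1, 0, 5)`).

The package implements, in closed form, the expression of `u_q(p)` as a
ratio of two quadratic forms in `p`,

    u_q(p) = (1/2 p Q p' + c p + a) / (1/2 p Q̄ p' + c̄ p + ā),

with coefficients polynomial in `q` and the payoffs. On top of this it
provides:

* **Best responses** (`best_response_candidates()`): the optimum of the mean
  utility over any opponent set lies in a discrete candidate set — the 16
  cube vertices plus, for every face of the cube, the interior stationary
  points of the restricted objective. The package enumerates this set
  (multi-start ascent per face, gradient-verified) and returns the argmax.
  A seeded Gaussian-process Bayesian optimiser
  (`best_response_bayesian()`) and an exhaustive `grid_oracle()` provide
  independent routes.
* **Distance from zero-determinant play** (`sse()`, `nearest_zd()`): the
  squared residual of projecting the transformed strategy
  `p̄ = (p1−1, p2−1, p3, p4)` onto the ZD subspace spanned by the columns of
  a payoff-difference matrix `C`; `SSE = 0` exactly for ZD (e.g.
  extortionate) strategies.
* **Moran processes with a re-optimising player**
  (`best_response_dynamics()`, `fixation_probability()`,
  `dynamic_moran_experiment()`): exact birth–death fixation probabilities
  for a best-response type that re-solves its strategy at every population
  composition, versus a frozen comparator.
* **A longer-memory benchmark** (`gambler_strategy()`,
  `optimise_gambler()`): a 17-parameter lookup strategy keyed on the
  opponent's first two moves and both players' last moves, trained by
  simulated play to probe what one-round memory leaves on the table.
* **Seeded experiment harnesses** (`run_sse_experiment()`,
  `run_moran_experiment()`, `run_gambler_experiment()`) and a thin CLI
  (`exec/memone`).

## Worked example

```r
library(memone)

opp <- rbind(c(0.322, 0.908, 0.446, 0.862),
             c(0.657, 0.773, 0.692, 0.047))
br <- withr::with_seed(1, best_response_candidates(opp))
br
#> Best response (candidates): p* = (0, 0, 0, 0.602423), mean utility 3.655025
sse(br$p_star)
#> [1] 0.4217365
```

The best response to this opponent pair defects after every outcome except
mutual defection, where it cooperates with probability 0.60 — an interior
stationary point on the face `p1 = p2 = p3 = 0` (not a cube vertex, and with
SSE 0.42 far from any zero-determinant strategy, so optimal play here is not
extortionate). The reported mean utility 3.66 is the average long-run payoff
per round against the two opponents.

From the shell, the same computation:

```sh
exec/memone best-response --opponents opponents.csv --seed 1
exec/memone sse --strategy 1,0,1,0        # Tit-for-Tat: SSE 0 (a ZD strategy)
exec/memone moran --opponent 0.6,0.2,0.7,0.3 --n 4 --seed 2
```

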