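---
title: "Best-response memory-one strategies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-response memory-one strategies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memone)
```

This vignette documents the models implemented in `memone`, the numerical
choices behind them, and what the package's tests do and do not establish.

## The match model

Two memory-one players are fully described by cooperation probabilities
conditioned on the previous round's joint outcome. With states ordered
(CC, CD, DC, DD) from the focal player's perspective, a match is a 4-state
Markov chain; the focal player's long-run payoff per round is the
stationary distribution dotted with `(R, S, T, P)`. The payoff constants
satisfy `T > R > P > S` and `2R > T + S`; the package defaults to the
conventional `(R, P, S, T) = (3, 1, 0, 5)` and all of the experiment
harnesses use those values.

Two routes to the same utility coexist deliberately:

* `utility_markov()` builds the transition matrix and solves `vM = v` with a
  normalisation row (degeneracy is detected by a singular-value test at
  tolerance `1e-8`: a stationary eigenspace of dimension above one raises a
  typed error rather than returning an arbitrary eigenvector).
* `utility_quadratic()` evaluates the closed form: a ratio of two quadratic
  forms in the player's vector, with coefficients polynomial in the opponent
  and the payoffs.

The suite cross-checks the two on a thousand random pairs to `1e-8`; the
closed form is what every optimiser in the package differentiates.

### Degenerate matches

Deterministic strategy coordinates can make the match chain reducible; the
quadratic denominator then vanishes (tolerance `1e-12`, the double-precision
scale of the polynomials involved). Where a long-run value is still wanted —
notably self-play `u_p(p)` inside the Moran machinery — the package takes
the trembling-hand limit: every coordinate is mapped to
`x(1 - 2ε) + ε` with `ε = 1e-6` before solving. Pairs of near-vertex
strategies can leave the perturbed denominator at the `ε²` scale, below the
degeneracy tolerance, so internal fallbacks widen `ε` progressively
(`1e-6`, `1e-4`, `1e-3`, `1e-2`) and keep the first value that is
well-defined; the coarsest rung changes utilities by at most a few times
`1e-2`, which is immaterial where it is used (ranking candidates during
ascent). Note that degeneracy is not confined to vertex pairs: the strategy
`(1, 1, 0, 0)` (repeat your own last move) splits the chain into two closed
classes against *every* opponent.

## Best responses

The mean utility against `N` opponents is a sum of quadratic-form ratios —
non-concave, with multiple local optima (against a cooperator, the defector
and the printed alternatives `(1/2, 0, 0, 0)` and `(1/2, 0, 0, 1/2)` are all
optimal). The candidate-set search rests on the fact that the optimum over
the cube lies either at a vertex or at a point that is stationary in its
free coordinates on some face. `candidate_set()` therefore enumerates the
16 vertices plus, for every proper subset of pinned 0/1 coordinates (65
face/assignment combinations), the interior stationary points of the
restricted objective.

Stationary points are found by multi-start bounded quasi-Newton *ascent* of
the face-restricted objective (a deterministic centre start plus, by
default, 32 Latin-hypercube starts), not by polynomial root-finding of the
cleared first-order system. Two reasons:

* For several opponents, the printed "cleared" stationarity polynomial
  (exposed as `stationarity_residual()`) clears each opponent's denominator
  only against its own term; its zero set coincides with the gradient's only
  for a single opponent. The search therefore verifies the *gradient* of the
  restricted objective (`< 1e-8` in sup norm) at every accepted point.
* Stationary points that are not local maxima (saddles, minima) can never be
  the argmax, so ascent loses nothing that matters for the search's
  soundness, which the suite checks against an exhaustive `21^4` grid.

Points converging to a face boundary are discarded (the finer face owns
them); near-duplicates are merged at `1e-6`. Ties in the final argmax
(within `1e-9`) are broken toward the lexicographically smallest vector,
for reproducibility. One consequence worth knowing: the tournament optimum
is frequently *non-unique* (flat optimal sets are common — e.g. the
all-defect corner tied with near-`(1,1,0,0)` strategies), and summary
statistics of "the" best response depend on which optimum a solver reports.
The tie-break makes the candidate solver's choice deterministic; the
Bayesian solver lands wherever its search happens to settle on the flat
set, which is also how the SSE distribution experiment behaves when driven
by black-box optimisation — `run_sse_experiment()` exposes both methods.

`best_response_bayesian()` is a compact Gaussian-process
expected-improvement optimiser (squared-exponential kernel with a
median-distance lengthscale, EI maximised over a seeded candidate pool of
fresh Latin-hypercube draws plus jitter around the incumbent, 16-point
initial design, 64-evaluation budget, projected-gradient polish). It is
written in-package and kept deliberately small; it is deterministic given
its seed.

## Distance from zero-determinant behaviour

In the coordinates `p̄ = (p1 − 1, p2 − 1, p3, p4)` the ZD strategies form
the column space of the 4×2 payoff-difference matrix with rows
`(R−P, R−P)`, `(S−P, T−P)`, `(T−P, S−P)`, `(0, 0)`. `nearest_zd()` computes
the least-squares projection via a QR factorisation (the explicit
normal-equation inverse is the definition, not a numerical recipe), and
`sse()` returns the squared residual. The projection is unconstrained: no
sign restrictions are imposed on the ZD coordinates, so the statistic
measures distance from the ZD-consistent subspace as a whole, not from the
extortionate cone specifically. Because the fourth row of the matrix is
zero, `SSE ≥ p4²` always — cooperating after mutual defection is the most
"non-ZD" thing a strategy can do.

## Moran processes and the dynamic player

In a population of `n` individuals (default `n = 4`, the smallest size
exposing starting counts `K ∈ {1, 2, 3}`) with `K` best-response players
and `n − K` residents `q`, fixation probabilities follow the standard
birth–death formula with `γ_i` the ratio of down- to up-transition
probabilities, themselves built from the per-composition payoff matrix
(`composition_payoffs()`: self-play and cross-play long-run utilities, in
the trembling-hand limit where degenerate).

The *dynamic* player re-solves its strategy at every composition via
`best_response_dynamics()`: a fixed-point iteration that starts from a
seeded uniform draw and repeatedly maximises
`mean utility against the opponents + K_self · u_frozen(p)` with the
self-copy frozen at the previous iterate (inner argmax: vertex enumeration
plus multi-start projected ascent). The self-interaction count at
composition `K` is `K − 1`, consistent with the fitness
`f1 = (K−1)A11 + (n−K)A12`. The iteration stops when successive iterates
move less than `1e-4` in sup norm (at most 50 iterations). Best-response
iterations can cycle — an exploit-your-own-copy / cooperate-with-yourself
oscillation is common — in which case the iterate with the highest
self-interaction objective is returned and flagged as non-converged.

Two design points were genuinely open and are worth recording:

* *Objective weighting.* The self-interaction objective weights the (single)
  opponent with 1 while the fitness weights it with `n − K`; for `n = 4`
  the two weightings disagree only at `K = 2`. We measured the
  fitness-consistent alternative (relative self-weight `(K−1)/(n−K)`) and
  found the same qualitative behaviour, including occasional fixation
  ratios below one: a strategy maximising its own payoff can raise the
  resident's fitness even more (cooperative optima are exploitable), which
  depresses its fixation probability regardless of the weighting. The
  implementation keeps the plain `K − 1` self-count.
* *The static comparator.* `dynamic_moran_experiment()` freezes the
  strategy optimised at a reference composition `K0` (default 1) and reuses
  it at every composition; `K0` is exposed because freezing the
  per-`K`-optimised strategy instead is an equally defensible reading, and
  we measured both to behave similarly on random opponents.

The suite verifies the fixation formula against an independently coded
absorption linear solve, checks neutral drift (`x_K = K/n`) to `1e-12`,
and checks that on seeded random opponents the mean dynamic/static ratio
exceeds one. Individual ratios *below* one do occur — adaptation to the
population density is not uniformly beneficial under this objective — and
the experiment records them rather than filtering them.

## The Gambler and the price of short memory

The `(2, 1, 1)` Gambler conditions on the opponent's first two moves, the
opponent's last move and its own last move: 16 lookup probabilities plus an
opening probability. Conventions the model text leaves open:

* On the first move the opening probability applies; on the *second* move
  the opponent has only one recorded move, so the first-two-moves key is
  incomplete and the opening probability applies again; the table takes
  over from move three. This is the simplest convention and is applied
  uniformly.
* A memory-one player in simulation cooperates on its first move. Long-run
  analytic utilities are opening-independent, so this matters only at the
  `1/turns` scale.

`simulate_match()` plays repeated matches vectorised across repetitions
(the analytic route cannot price a longer-memory player). The paper-scale
default is 500 turns × 200 repetitions; the experiment harness and tests
use a fast 100 × 20 profile, whose sampling error on a per-turn mean is
about 0.03, and the dominance checks carry exactly that slack.
`optimise_gambler()` estimates the best Gambler by the same
expected-improvement optimiser in 17 dimensions, with every candidate
evaluated under common random numbers (one simulation seed per
optimisation) so the objective is deterministic. The initial design is
warm-started with the memory-one best response *embedded* as a Gambler
(memory-one strategies are exactly the Gamblers that ignore the opening
key), so the optimised Gambler can never be reported worse than the best
memory-one strategy by more than simulation noise — the dominance being
probed is a property of the strategy spaces, and the warm start keeps it
from being confounded with optimiser luck at reduced budgets.

## The opponent generator

All experiments draw opponents i.i.d. uniformly on `[0,1]^4`
(`sample_opponents()`), the maximum-entropy model of a "random memory-one
strategy", with per-trial sub-seeds derived from one experiment seed. This
emulates unstructured opponent pools; it does not emulate named tournament
strategies, correlated populations, or noisy execution, so passing tests
say nothing about those regimes. Experiment scales are deliberately
desk-sized — 100 SSE trials, 20 Moran trials at `n = 4`, 3 Gambler trials
at the fast profile — and every harness takes a `trials` argument for
larger runs.

## Known limitations

* The candidate search guarantees coverage only up to the multi-start
  heuristic on each face; the suite bounds the risk empirically against a
  fine grid rather than algebraically.
* Execution noise (trembling during play, as opposed to the trembling-hand
  *limit* used for degenerate chains) is not modelled.
* The Moran machinery assumes a well-mixed population of two types with
  exact fixation formulas; no mutation, selection-intensity scaling, or
  structured populations.
* `stationarity_residual()` is the per-opponent cleared polynomial; treat
  it as an identity check per opponent, not as the multi-opponent
  first-order condition (use `utility_gradient()` for that).
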