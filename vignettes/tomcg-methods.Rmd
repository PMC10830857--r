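---
title: "Methods: recursive Theory of Mind in centipede games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recursive Theory of Mind in centipede games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomcg)
```

## The games

A centipede game runs over `L` alternating decision steps (Player 1 at odd
steps, Player 2 at even; `L` even so Player 2 owns the last move). The
incremental variant `icg(L, M, growth, split)` starts from a resource `M`
that is multiplied by `growth` at every step; the player taking at step
`l` receives a `split` fraction of `growth^(l-1) * M`, the other player
the remainder. If Player 2 postpones at step `L`, one final growth is
applied and Player 1 receives the `split` fraction. The default
parameterization (`M = 0.5`, doubling, 80/20 split) reproduces the payoff
ladder used in the classic 4- and 6-step laboratory experiments: the
temptation to wait doubles the pot each step, but waiting hands the move
to the co-player.

Constant-size variants — where only the division, not the pot, changes —
are supplied as explicit schedules through `centipede_game()`. The shipped
`ccg6_synthetic` preset is *synthetic*: an equal split at step 1 with a
taker share rising linearly to 80% at the pass-through. It is a stand-in
with the right qualitative structure (no growing temptation), not a
transcription of any experimental table; users calibrating against real
constant-size data should enter the published table via the
`ccg6_template.yaml` schema.

Payoffs are also stored as integers on a fixed decimal scale (`1e8`), so
the strict inequalities inside the reasoning kernels can never tie or flip
through floating-point representation.

## Strategies and reasoning processes

A strategy `(t, k)` couples a prior belief `t` — the earliest step at
which to take, with `t = L + 1` meaning never — to a recursion depth `k`.
A depth-`k` individual attributes `(t, k - 1)` to every co-player,
simulates the co-player's reasoning, and responds; the attribution bottoms
out at level 0, which simply acts on `t`. Seats alternate along the
recursion: the imagined reasoner at level `j` occupies the focal
individual's own role when `k - j` is even, the co-player's otherwise, so
level `k` is always evaluated in the role the individual is about to play.
This alternation is implied by the model's "she believes her co-player
reasons one level below her" structure, and the package computes separate
threshold distributions for the two roles.

Each level applies a reasoning-process kernel to the believed co-player
threshold `c`:

* **unconditional** — respond `max(c - 1, 1)`;
* **conditional** — compare the taker's share at `c - 1` (preempting)
  with the non-taker's share when the game ends at `c` (waiting); adopt
  whichever threshold pays more, ties resolving to the earlier take;
* **inertia** — preempt only on a *strict* gain; otherwise keep the
  threshold this reasoner inferred two levels down (her previous own
  inference), initialized to the prior `t`.

Three conventions deserve explicit statement because the verbal model
under-determines them:

1. *Payoff comparisons run on the game-ending-step scale.* The preempt
   value is the taker's share at step `c - 1` and the wait value the
   non-taker's share at step `c`, regardless of which seat owns those
   steps; when `c = L + 1` the wait value is the reasoner's role share of
   the pass-through. This is the only reading we found that reproduces
   the canonical worked recursion in both roles.
2. *No preemption below step 1.* At `c = 1` the conditional kernel
   returns 1 and the inertia kernel falls back to the previous inference.
   This fallback is what lets an inertia reasoner end up acting on her
   original belief, and it is required to reproduce the documented
   four-threshold error support of strategy (3,2).
3. *The pass-through comparison is role-specific.* A Player-1 reasoner
   facing an always-postponing co-player keeps her plan (the favored pass
   share beats taking at step `L`), while a Player-2 reasoner preempts.
   This asymmetry is the source of the optimistic never-take behavior of
   high-`t` strategies in the Player-1 role.

## Cognitive errors

At every recursion level `1..k` (not level 0: the prior is a belief, not a
computation) the kernel output `x` is replaced by `x - 1` with probability
`eps`, by `x + 1` with probability `eps`, and kept with probability
`1 - 2*eps`; values outside `[1, L + 1]` are clamped to the boundary and
their mass merged there. The per-direction parameterization (rather than
`eps/2` per side) is adopted because it reproduces the published
regime-change points of the two-strategy gradient analysis on the printed
ε grid; the two conventions coincide under a relabeling `eps -> eps/2`,
so only the scale of ε, not the model, is at stake. The valid domain is
`0 <= eps <= 0.5`.

`threshold_distribution()` enumerates the branching tree exactly over the
joint state (previous inference, current inference) — at most `(L+1)^2`
states per level — so no sampling error enters the analytic pipeline;
`sample_thresholds()` draws realizations for the Monte Carlo path and is
tested against the exact distribution by goodness of fit.

## From thresholds to actions and payoffs

A threshold maps to the smallest step the acting role owns that is at
least the threshold; thresholds past the role's last seat map to never
taking. Expected payoffs between strategies average the two role
assignments, each an exact sum over the product of the two players'
action distributions (`exact_fitness()`), or the corresponding Monte
Carlo estimate with fresh per-repetition samples (`mc_fitness()`,
default `R = 5e4`). The exact engine is the default everywhere because it
is deterministic and reproducible; the sampler exists for fidelity to the
original estimation procedure and as a cross-check. An optional cost
`c * k` per reasoning level is subtracted after role averaging; the
default is 0.

## Evolutionary dynamics

Imitation follows the Fermi rule `p = plogis(beta * (f_rm - f_focal))`.
With rare mutations the population is monomorphic between fixation
events, giving an embedded Markov chain over the `n_S` homogeneous
states with `Gamma[i, j] = rho[i, j] / (n_S - 1)` and the diagonal
absorbing the remainder. Fixation probabilities use the birth–death
closed form with log-space accumulation (clamped through `logsumexp`), so
selection strengths up to `beta = 10` at `Z = 500` remain well
conditioned; they are verified against brute-force absorbing-chain solves
for `Z <= 12`. The stationary distribution solves the left fixed-vector
linear system directly (no eigen-iteration) — exact and reproducible for
the `n_S <= 49` spaces used here. Composition-dependent fitness excludes
self-interaction (denominator `Z - 1`), the standard finite-population
convention.

The gradient of selection for a strategy pair is
`G(i) = (i/Z)((Z-i)/Z) * tanh(beta * (f_A(i) - f_B(i)) / 2)`; on the
discrete grid a sign change `- -> +` (as `i` grows) is reported as a
repeller at the midpoint, `+ -> -` as an attractor. Evolutionary
robustness demands every mutant's fixation probability be strictly below
`1/Z`, with a `1e-12` relative margin; exact equalities are reported as
neutral edges.

The agent-based simulator (`simulate_moran()`) implements the same
process with explicit mutation probability `mu`, computing fitness from
the precomputed payoff matrix and current counts (not replaying games),
recording every `Z` updates. It runs in compiled code on R's own RNG
stream, so a `set.seed()` call makes entire trajectories bit-for-bit
reproducible.

## Calibration

`model_step_distribution()` converts a stationary distribution into the
observable distribution of game-ending steps (self-play of each
monomorphic state, both roles sampled independently), and
`fit_step_distribution()` grid-searches `(beta, eps)` against an
empirical ending-step table, reporting the full distance surface. The
distance is least squares over ending-step categories by default with a
Kullback–Leibler option; the original fitting procedure's metric is not
specified, so both are exposed and reported. Synthetic fixtures
(`simulate_step_fixture()`) draw multinomial samples of `n` games from a
model distribution; parameter-recovery tests use them in place of
external experimental tables, which are referenced by citation only and
accepted as user-supplied CSV input.

At realistic fixture sizes the fitted parameters are identified only up
to a diagonal ridge (larger β compensated by larger ε), so the recovery
tests use a grid whose cell size matches the sampling uncertainty of an
`n = 200` fixture (steps of 0.2 in β and 0.1 in ε): on that grid the
generating point is recovered within one cell in effectively all
replicates, while finer grids mostly resolve noise along the ridge.

## Problem sizes and test design

The test-suite defaults are chosen for a desk-scale analysis: the full
4-step strategy space (25 strategies) everywhere; chains at `Z = 500` for
headline results and `Z = 50` where many chains are built; the agent-based
validation at `Z = 50`, `mu = 1e-3`, `4e8` updates (a few tens of seconds
compiled), which brings the time-averaged frequencies within 0.04 total
variation of the embedded-chain prediction; Monte Carlo fitness checks at
the canonical `R = 5e4`. The synthetic-data generator for calibration
emulates multinomial sampling of ending steps only — it does not model
subject heterogeneity, learning across rounds, or role asymmetries in
real experiments, so passing recovery tests demonstrate internal
consistency of the pipeline, not fidelity to any particular dataset.

## Known limitations

* The inertia reasoning process as reconstructed here reproduces the
  model's documented reasoning examples, error supports, and the
  two-strategy coordination analysis (regime changes at ε = 0.06 and
  ε = 0.12 on the 0.02 grid at `Z = 500`, `beta = 0.31`), but *not* the
  reported evolutionary robustness of the optimistic strategy (5,3) at
  strong selection: under these conventions a handful of
  intermediate-belief strategies — (3,0) foremost — earn more against a
  monomorphic (5,3) population at ε = 0.19 than (5,3) earns against
  itself, because (5,3)'s Player-1 distribution retains substantial
  never-take mass that late takers exploit. We examined the convention
  space (role anchoring, kernel payoff framings, boundary handling,
  error parameterizations) and found no variant satisfying both the
  printed pairwise results and that robustness claim; the corresponding
  acceptance test is left failing by design, and the invasion table is
  available from `is_evolutionarily_robust()` for inspection.
* Beliefs are fixed for life: no updating within or across interactions,
  no inference of a co-player's actual depth, and a single shared
  reasoning process per population.
* The population is well mixed; no structure, assortment, or
  multi-mutant coexistence beyond the two-strategy chain.
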