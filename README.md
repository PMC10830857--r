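# tomcg — evolution of recursive Theory of Mind in centipede games

`tomcg` asks how a capacity to reason about other minds can evolve by
natural selection. It models a finite, well-mixed population whose members
repeatedly play a centipede game — a sequential dilemma in which two
players alternate between **T**aking the larger share of a resource (ending
the game) and **P**ostponing (letting the resource grow, at the risk that
the other takes first). Backward induction says a rational player takes
immediately; humans reliably do not. The package is aimed at researchers in
evolutionary game theory and behavioral science who want to reproduce,
probe, or extend this class of models.

## The model

A strategy is a duple **(t, k)**:

* **t ∈ {1, …, L+1}** — a prior belief: the earliest step at which to play
  T (`t = L + 1` means always postpone);
* **k ≥ 0** — a Theory-of-Mind depth: a (t, k) individual believes every
  co-player uses (t, k−1) and computes a response to that anticipated
  behavior, recursively down to the naive level-0 belief.

Three *reasoning processes* (RPs) turn the believed co-player threshold `c`
into a response at each recursion level: **unconditional** (always preempt:
`c − 1`), **conditional** (preempt when the taker share at `c − 1` beats
waiting for the game to end at `c`), and **inertia** (preempt only on a
strict payoff gain, otherwise keep what was inferred at the previous own
reasoning level — possibly the original belief). At every level the
computed threshold is perturbed one step down or up with probability ε
each, producing a branching process and hence an exact probability
distribution over thresholds — a mixed strategy.

Fitness of X against Y is the expected game payoff with X playing both
roles (f_{X,Y} as a role-averaged expectation, or the Monte Carlo estimator
with R = 5×10⁴ samples). Evolution follows the Fermi pairwise-comparison
rule p = (1 + e^{−β·Δf})⁻¹ at selection intensity β. In the rare-mutation
limit the dynamics reduce to a Markov chain over monomorphic states with
transition matrix Γ_{ij} = ρ_{ij}/(n_S − 1), whose stationary distribution
σ, marginals over t, k and realized take steps, gradients of selection
G(i) = T⁺(i) − T⁻(i), and evolutionary-robustness reports the package
computes analytically. An Rcpp agent-based simulator with explicit
mutation probability μ validates the analytics, and a grid-search
calibrator fits (β, ε) to empirical game-ending-step distributions.

## Worked example

The canonical illustration: Alice holds strategy (3, 2) in the 4-step
incremental game (resource 0.5, doubling each step, 80% to the taker).
She believes Bob uses (3, 1); reasoning without errors she concludes Bob
would take at step 2, so she takes at step 1:

```r
library(tomcg)
g <- icg(4)
threshold_trace(tom_strategy(3, 2), g, "inertia", role = 1)
#> level0 level1 level2
#>      3      2      1
```

With cognitive errors (ε = 0.19) the same recursion spreads over exactly
four thresholds, and as Player 1 (who moves at steps 1 and 3) that mixed
belief becomes a take-step distribution:

```r
d <- threshold_distribution(tom_strategy(3, 2), g, "inertia", eps = 0.19, role = 1)
round(unclass(d), 4)
#>      1      2      3      4      5
#> 0.5383 0.2717 0.1539 0.0361 0.0000
round(unclass(action_distribution(d, role = 1, game = g)), 4)
#>      1      3  never
#> 0.5383 0.4256 0.0361
```

Evolutionary analysis of the full 25-strategy space, and the coordination
dynamics between the rational strategy (1,0) and the optimistic reasoner
(5,3):

```r
pm <- payoff_matrix(strategy_set(g), g, "inertia", eps = 0.19)
ch <- embedded_chain(pm, Z = 500, beta = 0.31)
stationary_marginals(ch, g, "inertia", 0.19)$avg_k   # mean reasoning depth
#> [1] 1.002731

pair <- payoff_matrix(list(tom_strategy(1, 0), tom_strategy(5, 3)), g, "inertia", 0.19)
gradient_of_selection(pair, "(5,3)", "(1,0)", Z = 500, beta = 0.31)
#> Gradient of selection: (5,3) (focal) vs (1,0), Z = 500, beta = 0.31
#>      i     type
#>  158.5 repeller
```

The repeller at i ≈ 158 of 500 means a population needs about 32% (5,3)
players before selection carries it the rest of the way — the coordination
threshold between the rational equilibrium and the optimistic one. A
command-line front end (`inst/exec/tomcg`) exposes the same operations as
`reason`, `fitness`, `evolve`, `gradient`, `sweep`, `simulate` and `fit`
subcommands; YAML presets `icg4`, `icg6` and a synthetic constant-size
schedule ship in `inst/extdata/`.

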