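# exna — excitable network attractors in CTRNNs

`exna` builds continuous-time recurrent neural networks (CTRNNs) whose
input-free dynamics *realise* a prescribed directed graph as an **excitable
network attractor**: one stable equilibrium per graph vertex, and an
excitable connection along every graph edge. Perturbing the system at an
equilibrium by more than a threshold `δ` — with a deliberate input pulse or
with noise — triggers a fast, reliable transition to the next state, so the
continuous dynamics executes finite-state, input-dependent computation on
the graph. The package is aimed at researchers in nonlinear and
computational neuroscience who want a concrete, verifiable bridge between
graph-level descriptions of sequential computation and continuous neural
dynamics.

## The model and the construction

The network is the classical CTRNN

```
dy_i/dt = -y_i + Σ_j w_ij φ(y_j) + I_i(t),
```

with a sigmoid activation `φ` of threshold `θ` and maximal slope `1/(4ε)`,
in a smooth (logistic) and a piecewise-affine variant. Given a directed
graph with adjacency `a_ij` that contains no self-loops, no two-cycles and
no Δ-cliques (triples `i→j, i→k, j→k`), the coupling matrix is synthesised
from just four numbers:

```
w_ij = w_t + (w_s − w_t)·[i = j] + (w_p − w_t)·a_ji + (w_m − w_t)·a_ij .
```

A parameter recipe maps a target excitability threshold `δ ∈ (0, 1/2)` to

```
ε = δ/8,  θ = 1/2,  w_s = 1,  w_t = 0,
w_p = θ − δ/2,  w_m = −(w_s − θ) − δ/2 ,
```

under which (piecewise activation) the equilibrium with vertex `k` active
is the *exact* point with components `Y_A = w_s` (Active cell), `Y_L = w_p`
(Leading cells, edges out of `k`), `Y_T = w_m` (Trailing cells, edges into
`k`) and `Y_D = w_t` (everything else). Whether a connection is *excitable*
(needs a kick) or *spontaneous* (fires by itself) is governed by a
saddle-node bifurcation in `w_p`; for the three-cycle the fold happens on
an invariant circle (SNIC), replacing the equilibria with a periodic orbit
whose period diverges at threshold. The package computes these thresholds
in closed form and numerically, simulates the deterministic and noisy
(Euler–Maruyama) dynamics, extracts symbolic itineraries, and verifies
realisations kick-by-kick.

## Worked example

Realise the four-vertex Kirk–Silber graph (edges 1→2, 2→3, 2→4, 3→1, 4→1 —
vertex 2 chooses between two successors), then drive a walk through it:

```r
library(exna)

g <- graph_kirk_silber()
validate_graph(g)
#> <exna_violations> admissible: TRUE

p <- recipe_params(0.4)          # excitability threshold delta = 0.4
W <- build_weight_matrix(g, p)
W
#> <exna_weights> 4 cells
#>      1    2    3    4
#> 1  1.0 -0.7  0.3  0.3
#> 2  0.3  1.0 -0.7 -0.7
#> 3 -0.7  0.3  1.0  0.0
#> 4 -0.7  0.3  0.0  1.0

pw <- params_activation(p, "piecewise")
verify_realisation(g, p, pw, delta = 0.4)
#> <exna_realisation> delta = 0.4 - realised: TRUE
#> # A tibble: 1 × 6
#>   realised delta n_edges n_connected n_non_edges n_returned
#>   <lgl>    <dbl>   <int>       <int>       <int>      <int>
#> 1 TRUE       0.4       5           5           7          7

execute_walk(g, p, pw, c(1, 2, 4, 1), amplitude = 0.5)$success
#> [1] TRUE
```

All five graph edges are excitable connections (a kick of size 0.4 on the
target cell moves the system to the next state), all seven non-edge kicks
fall back to their source, and an input-pulse protocol steers the network
around the chosen branch at vertex 2. The bifurcation thresholds for the
default smooth parameters:

```r
bifurcation_thresholds(construction_params(0.05, 0.5, 1, -0.7, 0.3, 0))
#> <exna_bifurcation>
#>   w_p fold (closed form): 0.302713
#>   w_p fold (numeric):     0.302879
#>   w_p SNIC (3-cycle):     0.302879
#>   w_p fold (two leading): 0.30285
```

so at `w_p = 0.3` the network is excitable but close to threshold; above
`w_p ≈ 0.3029` the three-cycle switches by itself.

A shell interface wraps the same functionality
(`Rscript inst/cli/exna-cli.R verify --fixture three-cycle --delta 0.4
--activation piecewise`); see `?run_cli`.

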