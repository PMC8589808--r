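---
title: "Designing excitable network attractors in CTRNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing excitable network attractors in CTRNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exna)
```

## The model

A continuous-time recurrent neural network (CTRNN) couples $N$ scalar cell
activations through a saturating nonlinearity:

$$\dot y_i = -y_i + \sum_j w_{ij}\,\varphi(y_j) + I_i(t),$$

where $\varphi$ is a sigmoid with threshold $\theta$, maximal slope
$1/(4\varepsilon)$ and $\varphi(\theta) = 1/2$. Two activation kinds are
provided: the logistic (`smooth`) sigmoid
$\varphi_S(y) = [1 + e^{-(y-\theta)/\varepsilon}]^{-1}$, strictly
increasing with range $(0,1)$, and a piecewise-affine (`piecewise`)
variant that saturates *exactly* at 0 and 1 outside
$|y-\theta| \le 2\varepsilon$. Exact saturation is what makes the designed
equilibria exact fixed points, so the piecewise kind is the one for which
the construction can be verified with machine-zero residuals; the smooth
kind is an $O(\varepsilon)$ perturbation of it and is the one used for
bifurcation analysis, since it is invertible and admits the coordinate
change $J_i = \varphi(y_i)$,

$$\dot J_i = \tfrac{1}{\varepsilon} J_i (1-J_i)
  \bigl(-\varphi^{-1}(J_i) + \sum_j w_{ij} J_j\bigr),$$

valid input-free on the open cube $(0,1)^N$. The package integrates both
forms (`simulate_ode()`, `simulate_ode_J()`); inputs are deliberately
unsupported in $J$-coordinates because the transformed equation is derived
for the input-free system only.

## From a graph to a coupling matrix

The design target is a directed graph $G$. Vertices become stable
equilibria, edges become *excitable connections*: a perturbation of size
$\delta$ applied at the right cell moves the trajectory from one
equilibrium into the basin of the next. Three motifs must be absent for
the construction's cell-role bookkeeping to be well defined: self-loops,
two-cycles, and Δ-cliques (triples $i\to j$, $i\to k$, $j\to k$).
`validate_graph()` certifies this, listing every violating vertex, pair
and ordered triple; Δ-clique triples are reported exactly as ordered
instances, without collapsing relabellings, so the report can be checked
directly against the adjacency.

The coupling matrix uses four values only:

$$w_{ij} = w_t + (w_s-w_t)\delta_{ij} + (w_p-w_t)a_{ji} + (w_m-w_t)a_{ij},$$

so each cell self-excites with $w_s$, receives $w_p$ from the currently
active cell if it is next in the graph (its *Leading* input), $w_m$ if it
precedes it (*Trailing*), and $w_t$ otherwise (*transverse*). The recipe
(`recipe_params()`) maps a target threshold $\delta \in (0, 1/2)$ to

$$\varepsilon = \delta/8,\quad \theta = 1/2,\quad w_s = 1,\quad w_t = 0,
\quad w_p = \theta - \delta/2,\quad w_m = -(w_s-\theta) - \delta/2,$$

exactly (no floating-point rearrangement), under which the equilibrium
$\xi_k$ with vertex $k$ active has components $Y_A = w_s$, $Y_L = w_p$,
$Y_T = w_m$, $Y_D = w_t$ by role. Every component then sits strictly
beyond the piecewise corners ($|Y - \theta| > 2\varepsilon$), the residual
of the field is identically zero and the Jacobian is $-I$ — properties the
test suite asserts for randomly generated admissible graphs, not just the
shipped fixtures. Per-edge leading weights ($w_p$ overrides keyed by graph
edge) are supported because branching vertices are usefully detuned by
small asymmetries $\Delta w$; an override for edge $k \to l$ replaces only
the entry $w_{lk}$, and the predicted leading level of cell $l$ moves with
it.

When parameters are supplied directly rather than via the recipe, no
relation among them is enforced: validity for a particular graph is
established downstream by `verify_realisation()`, reflecting the fact that
the recipe point sits inside an open parameter set with the same
qualitative behaviour.

## Verifying a realisation

`test_connection()` implements the defining experiment: start at
$\xi_k$, add $\delta$ to cell $l$, integrate input-free, and classify the
outcome. The classification machinery declares settlement when the
trajectory stays within max-norm $\delta/4$ of a candidate equilibrium
continuously for 5 time units; candidates are the $N$ per-vertex
equilibria (exact for the piecewise recipe, Newton-refined for the smooth
kind) plus the rest state near the origin. The $\delta/4$ ball is small
against the $O(\theta)$ separation between equilibria and large against
integration error; 5 time units is several relaxation times of the
linearised dynamics (eigenvalues $\approx -1$), so mistaking a slow
transit for settlement would require the field to be anomalously small far
from any candidate. For a zero-amplitude kick the ball is floored at
$10^{-8}$ so the degenerate case classifies as returned with zero transit
time. The default horizon is 200 time units; transits under the recipe
take $O(1)$–$O(10)$, so the horizon is generous, and integration runs in
10-unit chunks with early termination, which keeps a full
all-ordered-pairs sweep (`verify_realisation()`) cheap even for the
50-random-graph property test.

`execute_walk()` composes connections under input control: a rectangular
pulse (default amplitude $\delta$, duration 1) on the target cell of each
step, with 40 time units of settling between steps. The walk succeeds when
the debounced single-active itinerary equals the requested vertex
sequence. Rectangular pulses rather than instantaneous kicks are used
because they are what an experiment or an upstream system can actually
deliver; an amplitude-$\delta$ pulse over one time unit delivers enough
charge to cross threshold because self-excitation takes over once the cell
passes $\theta$.

## Excitable versus spontaneous: the fold structure

With the smooth activation, the stable equilibria sit near a saddle-node
bifurcation in $w_p$. All fold computations reduce to the scalar map
$g(x) = \varphi^{-1}(x) - w_s x$, whose local extrema
$x_\pm = 1/2 \pm \sqrt{1/4 - \varepsilon/w_s}$ exist for
$w_s > 4\varepsilon$. Three related thresholds are computed:

* `wp_sn_closed_form()` — the asymptotic two-cell fold
  $w_p^{SN} = \varepsilon\log\varepsilon + \theta -
  \varepsilon(1+\log w_s) + \varepsilon^2/w_s$, truncated at the
  $\varepsilon^2$ term. At $(\varepsilon, \theta, w_s) = (0.05, 0.5, 1)$
  this gives $0.3027$ to four significant figures.
* `wp_sn_numeric()` — the exact two-cell fold, found by Newton iteration
  on the extended system (two equilibrium conditions plus vanishing
  Jacobian determinant) in $(J_1, J_2, w_p)$, seeded from the closed form
  and $x_-$, with a bisection-on-existence fallback. It returns
  $0.302879$, within $1.7\times10^{-4}$ of the truncation — consistent
  with the $O(\varepsilon^3)$ error order, which the tests check across
  $\varepsilon \in \{0.05, 0.025, 0.0125\}$.
* `snic_threshold_cycle()` — the three-cycle threshold, located by
  bisecting $w_p$ on the existence of the stable one-active equilibrium
  (Newton refinement from the saturated prediction, accepted only if the
  solution is stable and stays within 0.25 of the seed, so a jump to a
  distant root counts as disappearance). Because the fold lies on an
  invariant circle (SNIC), the same value marks the birth of the periodic
  orbit; detection via equilibrium existence avoids boundary-value
  continuation entirely and reproduces the continuation value
  ($\approx 0.30287$) to $10^{-5}$.

`lemma2_positions()` gives the asymptotic location of the pair of
equilibria just below the fold,
$J_2 = \varepsilon/w_s \pm \sqrt{2\eta\varepsilon}/w_s$ at
$w_p = w_p^{SN} - \eta$, valid for $\eta \ll \varepsilon/4$; tests confirm
Newton-refined equilibria agree within $5\varepsilon^2$.

For a vertex with two outgoing edges, the two leading cells interact
through $w_t$ and the relevant equilibrium conditions on the active sheet
are $g(J_3) = w_{p_3} + w_t J_4$ and $g(J_4) = w_{p_4} + w_t J_3$.
`wp_sn_prime()` bisects on the existence of the solution with both cells
at low activation, solving the pair by projected Newton restricted to the
branch $(0, x_-]$ where $g' \ge 0$. The exact solution involves an
unilluminating quartic, so only the numerical route is provided. A design
note on consistency: these sheet equations idealise the active cell at
$J = 1$, whereas the full two-cell fold has it at $1 - O(10^{-4})$ for
$\varepsilon = 0.05$ (the gap is exponentially small in
$1/\varepsilon$, but not numerically negligible at this value). The two
formulations therefore agree to about $3\times10^{-5}$, not to machine
precision, and the tests assert agreement at $10^{-4}$. The directional
effects are exact, however: negative $w_t$ raises the threshold
(suppression), positive $w_t$ lowers it, and an asymmetry $\Delta w$
shifts the weaker edge's threshold down by $\approx \Delta w$.

## Stochastic dynamics and itineraries

`simulate_sde()` implements fixed-step Euler–Maruyama for additive noise
$\sigma\,dW_i$, one Gaussian increment per cell per step, default
$dt = 0.01$ — two orders below the relaxation time, and sufficient for the
qualitative transition statistics studied here since the noise is
additive. Paths are reproducible given a seed, and $\sigma = 0$ reproduces
the plain Euler path bitwise (the tests compare against an independent
Euler loop). No higher-order stochastic scheme is provided; transition
statistics are treated as qualitative throughout.

`itinerary()` reduces a trajectory to the symbolic level: a cell joins the
active set when $\varphi(y_j)$ rises through 0.8 and leaves when it falls
through 0.2. "Active" is inherently a band, not a point, so hysteresis is
the natural debouncing mechanism; 0.8/0.2 splits the saturated levels
($\varphi(Y_A) \approx 1$ against $\varphi(Y_L), \varphi(Y_T),
\varphi(Y_D) \approx 0$ under the recipe) with wide margins on both sides.
Trajectory output is sampled at spacing $\le 0.1$ so no activation episode
can be stepped over.

Two subtleties matter when counting multi-cell activity:

* During *every* handover along an edge $k \to l$ the incoming cell
  crosses the on-level before the outgoing cell reaches the off-level, so
  two-cell active sets $\{k, l\}$ lasting up to about one time unit are a
  normal part of single-state switching in all regimes.
  `double_activation_events()` therefore defines a genuine
  double-activation as an active set containing two *mutually
  non-adjacent* cells — e.g. $\{3,4\}$ in the Kirk–Silber network, whose
  vertices 3 and 4 share no edge — which is exactly the coexisting-active
  configuration that a sufficiently negative transverse weight suppresses.
* `transition_statistics()` counts an entry only if the active set
  persists for at least 1 time unit (configurable), so threshold chatter
  during switching does not inflate counts. Ratios are normalised over the
  named target sets.

`detect_bottlenecks()` finds the ghosts of destroyed equilibria in the
spontaneous regime: strict local minima of $|\dot y|$ along a trajectory
below a ceiling (default 0.2, well under the $O(1)$ transit speeds) and
above a floor (default $10^{-6}$, so actually resting at an equilibrium is
not a passage), merged within a 5-time-unit refractory window.

## Synthetic graphs: what they emulate and what they do not

`random_admissible_graph()` draws every ordered pair independently with a
given edge probability and rejects any draw containing a forbidden motif
(budget 10,000 attempts, then an error naming the budget) — a simple,
auditable null distribution. "No feed-forward structure" is read as strong
connectivity (every vertex can be revisited), checked when
`require_no_sink_subgraph = TRUE`; this is the strongest natural reading
and is kept optional because the realisation theorem itself does not need
it. Measurement during development showed the joint requirement
*admissible and strongly connected* is essentially unreachable by
independent-pair sampling at ten vertices (acceptance below $10^{-4}$ for
any edge probability), so the shipped ten-vertex fixture
`graph_ten_node()` uses its own documented construction: a random directed
Hamiltonian-cycle backbone — strong connectivity by construction — plus
independent extra edges at probability 0.08, rejection-sampled to
admissibility. It is a synthetic stand-in for the kind of larger network
the construction targets, not a sample from the independent-pair null.

These generators emulate the graph-topological conditions of the theory
exactly; they do not emulate anything about real neural data — no degree
heterogeneity beyond Bernoulli fluctuations, no spatial structure, no
weight noise other than the uniform per-edge $w_p$ draws used in the
ten-node experiments. Passing tests therefore certify the
construction-and-verification machinery, not any claim about biological
connectomes.

## Problem sizes and test scope

The test suite runs realisation sweeps over 50 random admissible graphs of
3–8 vertices (piecewise recipe, $\delta = 0.4$), full-pair verification of
the three-cycle and Kirk–Silber fixtures in both activation kinds, SNIC
regime-separation runs of 300–400 time units on a 5-point $w_p$ grid
approaching the threshold from above, and Kirk–Silber noise experiments
with $\sigma = 0.05$, ten seeds, 500 time units each — sizes chosen so the
full suite completes in about a minute while every claim is exercised
end-to-end. Two stochastic findings are documented rather than assumed: at
$w_t = -0.3$ no double-activation event occurs across all seeds, while at
$w_t = 0$, $w_p = 0.315$ each of $\{3\}$, $\{4\}$, $\{3,4\}$ is entered
from the bottleneck at vertex 2. On the ten-node fixture with per-edge
$w_p \sim U(0.30, 0.32)$ and $\sigma = 0.01$, suppression at $w_t = -0.3$
is again complete; with $w_t = 0$, double-activations at this weak noise
level did not occur in ten 500-unit runs under our weight draw — the
per-edge asymmetries resolve each branch before a joint activation can
build up — so the existence of double-activations without suppression is
demonstrated at $\sigma = 0.05$, where it is robust.

## Known limitations

* Only fold/SNIC thresholds are detected; no Hopf points, no
  saddle-nodes of periodic orbits, no two-parameter continuation, and no
  periodic-orbit branches — equilibrium-existence bisection replaces
  continuation throughout.
* Basin-of-attraction statements are sampled (the specific kicks
  $\xi_k + \delta e_l$), not certified; near-complete realisation is
  tested only in that sampled sense.
* The singular limit $\varepsilon \to 0$ (discontinuous activation) is
  out of scope, as are denser encodings with more than one designed
  active cell per state.
* The piecewise activation is continuous but not smooth; `lsoda` handles
  the corner crossings without event detection because the field stays
  Lipschitz, at the cost of locally reduced order — the tolerances
  (default $10^{-9}$) absorb this. The $y$- versus $J$-coordinate
  cross-check agrees to $\sim 10^3 \times$ the integrator tolerance, the
  amplification coming from the $1/\varepsilon$ factor in the $J$-form.
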