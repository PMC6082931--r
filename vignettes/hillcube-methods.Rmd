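---
title: "Methods: from Boolean logic to normalized HillCube dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Boolean logic to normalized HillCube dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillcube)
```

## Scope and model class

`hillcube` simulates Boolean models of cell signaling — the motivating
application is B-cell receptor (BCR) signaling and its disruption in primary
immunodeficiencies (PIDs) — in two complementary regimes:

1. **Discrete**: synchronous Boolean updates with exhaustive attractor
   enumeration.
2. **Continuous ("semi-quantitative")**: each Boolean update rule is
   transformed into a smooth rate law and the network is integrated as a
   system of ordinary differential equations (ODEs), following the
   HillCube/BooleCube construction popularized by the Odefy line of work.

Every model is a set of update rules in **sum-of-products (SOP)** form,

```
KIN = RELAY & !INH
TF3 = COREC | CA
```

i.e. each target is an OR of AND-clauses over possibly negated sources. Nodes
without a rule are *inputs*; in discrete simulation they hold their value, in
continuous simulation they have rate zero. Both the rule-text dialect above
and SBML-qual (Boolean, Level 3) are read and written; SBML function terms
that are not already in SOP are normalized by distributive expansion with a
clause-count cap (default 1024) so the canonical form is deterministic and
blow-up is bounded.

## Discrete dynamics

The synchronous step applies every rule to the *previous* state at once.
Attractors (fixed points and limit cycles) are found two ways, which the test
suite cross-checks against each other:

- `simulate_discrete()` walks a trajectory until a state repeats;
- `enumerate_attractors_exhaustive()` visits all `2^F` states for `F` free
  (unclamped) nodes, with path compression, and refuses more than 20 free
  nodes (about one million states) rather than silently running forever.

## Continuous dynamics

### BooleCube: multilinear interpolation

For a rule `B` with sources `x_1 … x_m ∈ [0,1]`, the BooleCube value is the
multilinear interpolation of the rule's truth table:

$$\bar B(x) = \sum_{c \in \{0,1\}^m} B(c)\; \prod_{i=1}^m x_i^{c_i} (1-x_i)^{1-c_i},$$

equivalently the expectation of the Boolean rule under independent Bernoulli
inputs. The implementation evaluates this by Shannon expansion (recursive
conditioning on one variable), which is algebraically identical to the
explicit `2^m`-corner sum; the tests keep a literal corner-sum oracle and
require agreement to `1e-12`.

### Normalized HillCube

Each input is first passed through a Hill function

$$f(x; n, k) = \frac{x^n}{x^n + k^n},$$

normalized by `f(1; n, k)` so that the transformed input is exactly 1 at
`x = 1`. Substituting the normalized inputs into the BooleCube gives the
**normalized HillCube** `B̃(x)`, which is sigmoidal in each input yet agrees
exactly with the Boolean rule at every corner of the unit cube — for *any*
valid `(n, k)`. As `n → ∞` it converges pointwise to the discrete rule away
from the threshold `k`.

### ODE form and integration

Each regulated node relaxes toward its rule value with a lifetime `τ_i`:

$$\frac{dx_i}{dt} = \frac{\tilde B_i(x) - x_i}{\tau_i}.$$

Defaults are `n = 3`, `k = 0.5`, `τ = 1`; `(n, k)` may be set per regulatory
edge and `τ` per node (`kinetic_parameters()`, with a JSON schema for files).
Edge-level tuning spans `n ∈ [1, 32]`, `k` up to `0.9`, `τ` up to `16` in the
shipped example file `inst/extdata/tuned_parameters.json`.

Integration uses `deSolve::ode` (lsoda, `rtol = atol = 1e-6`). Clamp windows
(knockouts/knockins/transient modulation) are handled as exact integration
breakpoints: at a window start the clamped node jumps to its clamp value and
its rate is frozen; at the window end it is released and relaxes under its
rule. States are clipped to the unit cube against integrator round-off.

A continuous attractor is declared by `find_steady_state()` when
`‖dx/dt‖∞ < tol` holds continuously for a window (default 10 time units);
the earliest qualifying sample is recorded as `entered_at`. Genuine
oscillators (e.g. a three-node negative-feedback ring at steep `n`) correctly
yield no steady state at tight tolerance. Note that a *two*-node negative
loop, though it cycles with period 4 discretely, spirals into the interior
fixed point `(0.5, 0.5)` continuously — the continuous relaxation damps it —
which is why the oscillation tests use the three-node ring.

## Perturbation analysis

A knockout clamps a node to 0 and a knockin to 1 for the entire run, with the
wild-type kinetic parameters retained. `run_pid_panel()` produces an
attractor matrix (wild-type row plus one row per perturbation) and
`compare_to_wildtype()` reports per-perturbation dysregulated nodes
(`|activity − wild-type| > threshold`) and discrete flips at the 0.5 cut.
`default_pid_panel()` encodes a 24-entry panel of PID-associated proteins
(20 knockouts including both CARD11 and NFKBIA loss-of-function, and 4
knockins: CARD11 gain-of-function, KRAS, NFKBIA gain-of-function, PI3K),
filtered with a warning to the nodes actually present in the loaded model.

`run_basin_protocol()` implements the transient-modulation experiment: run
freely to the activating attractor, clamp a set of modulator nodes to 1
during a window (default style `[110, 210]`), release, and test whether the
original attractor is re-entered (per-node tolerance 0.05).

## Structural analysis

The signed interaction graph collapses the AND-gate structure to one edge per
(source, target, sign); a source acting both positively and negatively on the
same target contributes two edges. Strongly connected components come from
`igraph`. Feedback loops are enumerated by a bounded Johnson-style search —
simple cycles anchored at their smallest vertex, depth-limited by
`max_length` and count-limited by `max_results` — because the installed
`igraph` lacks a simple-cycle routine. A cycle through a source–target pair
connected by both a `+` and a `−` edge is reported once with sign `NA`
(ambiguous). Per-node *loop participation* (fraction of loops through the
node) drives `rank_candidates()`, which proposes high-participation nodes not
already in a known-PID list as candidate disease genes.

## Synthetic models and the shipped fixture

`random_network()` draws a seeded random SOP network by wiring a random DAG
and then adding back-edges with probability `feedback_enrichment`, so cycle
content is controllable. Property tests use it to check, e.g., that every
generated network validates, round-trips through SBML-qual, and that discrete
fixed points are continuous steady states at steep `n`. These tests
demonstrate *internal consistency* of the two simulation regimes and the two
attractor routes; they do not, and cannot, validate biological parameter
choices.

`toy_bcr_network()` is a 13-node fixture with the qualitative shape of a
two-signal receptor cascade: two signals (`SIG1`, `SIG2`), a receptor/relay
chain, a kinase with a negative-feedback inhibitor, a calcium-like integrator
and three TF-role readouts. With both signals on, all three TFs activate;
knocking out the relay silences the relay-dependent TFs `TF1` and `TF2` while
`TF3` (driven by the costimulatory branch) stays on; a transient modulator
clamp diverts and then re-enters the activating attractor. The fixture is
deliberately *not* a reconstruction of any published B-cell model.

```{r fixture}
fx <- toy_bcr_network()
res <- run_scenario(fx$network, fx$params, fx$scenarios$both_on)
round(res$attractor$state[fx$tf_nodes], 3)
```

## Numerical choices and limitations

- lsoda with `rtol = atol = 1e-6`; sampled on a fixed grid (`sample_dt`)
  with clamp edges as hard breakpoints, so clamp discontinuities never pass
  through the integrator.
- Steady-state tolerance `1e-6` on the rate, sustained over a 10-unit
  window; re-entry tolerance 0.05 per node.
- Exhaustive attractor search is limited to 20 free nodes; cycle enumeration
  to `max_length` (default 26) and `max_results` (default 1e6), both hard
  errors rather than silent truncation.
- Synchronous updating only; asynchronous/probabilistic schemes are out of
  scope.
- The continuous regime is *semi-quantitative*: activities are normalized to
  `[0, 1]` and parameters are phenomenological, not fitted rate constants.
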