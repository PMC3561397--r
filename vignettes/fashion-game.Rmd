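---
title: "The fashion game: model, dynamics, and simulation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fashion game: model, dynamics, and simulation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fashiongame)
```

## The model

The fashion game is a binary-action game played on an undirected simple
network. Each agent $i$ holds an action $a_i \in \{0, 1\}$ and has a fixed
type: a **conformist** likes each neighbour who plays the *same* action,
a **rebel** likes each neighbour who plays a *different* action. Writing
$L_i$ for the number of liked neighbours and $d_i$ for the degree, agent
$i$'s utility is

$$u_i = L_i - (d_i - L_i) = 2L_i - d_i,$$

her **satisfaction degree** is $s_i = L_i / d_i$, and she is **satisfied**
iff $s_i \ge 1/2$, equivalently $u_i \ge 0$. A conformist–conformist pair
plays a coordination game, a rebel–rebel pair an anti-coordination game,
and a mixed pair matching pennies — which is why pure Nash equilibria (all
agents satisfied simultaneously) are not guaranteed: a single
conformist–rebel dyad already has none.

Four indices summarise a configuration or an ensemble of runs:

* **cooperation degree** — the fraction of satisfied agents; it equals 1
  exactly when the configuration is a pure Nash equilibrium;
* **average satisfaction degree** — the mean of $s_i$;
* **complete ratio** — the fraction of agents with $s_i = 1$;
* **equilibrium ratio** — across replicate runs, the fraction that end in
  a pure Nash equilibrium.

Ties are part of the model definition: an agent with $u_i = 0$ (possible
only at even degree) **counts as satisfied and never moves**. This single
threshold is encoded once, in `agent_satisfaction()` / the simulation
core, and everything else inherits it. Degree-0 agents, which rewiring
can produce, are defined completely satisfied with utility 0 (their
preference is vacuous).

## The dynamic

Time is discrete. At each step every agent evaluates her satisfaction
against the *previous* profile; each unsatisfied agent then flips her
action independently with the **updating probability** $p$, and all flips
are applied simultaneously. $p = 1$ is the fully synchronous best-response
dynamic; as $p \to 0$ at most one agent moves per step, the asynchronous
limit, which `run_dynamics(mode = "sequential")` exposes directly (one
uniformly chosen unsatisfied agent flips per step). Because satisfied
agents never move, a pure Nash equilibrium is absorbing for every $p$,
so index experiments stop early at absorption without changing any
final-step statistic; cycle studies (`detect_limit_cycle()`) disable the
early stop and instead iterate the deterministic $p = 1$ map until a
profile recurs.

Two structural facts anchor the test suite. For homogeneous populations
(all conformists or all rebels) the game is a potential game — each
single-agent improving flip strictly increases the count of concordant
(resp. discordant) edges — so sequential dynamics always absorb. And
under the synchronous map an all-rebel population always enters a limit
cycle of period 1 or 2 regardless of structure; mixed populations can do
worse (the conformist–rebel dyad cycles through all four profiles).

## Networks

Three generator families are provided.

* `make_torus_moore(rows, cols)` — the cellular-automata world: a torus
  lattice where each agent's neighbourhood is the eight touching cells
  (Moore neighbourhood), hence 8-regular with $4 \cdot rows \cdot cols$
  edges. Agent ids are 0-based, cell $(r, c)$ mapping to $r \cdot cols + c$.
* `make_ring_lattice(n, d)` — the regular benchmark ring: each agent
  adjacent to the $d/2$ nearest agents on either side.
* `rewire_ws(net, q)` / `make_small_world()` — Watts–Strogatz style
  randomisation: every edge is independently selected with probability
  $q$; a selected edge keeps one endpoint and has the other redrawn
  uniformly over agents. We keep the lexicographically smaller endpoint
  (the rewiring only needs *one* endpoint kept; any fixed convention
  yields the same ensemble statistics), walk edges grouped by
  neighbour-rank then agent id (the classical construction order), and
  reject self-loops and duplicate edges by resampling, up to 100 retries,
  after which the edge is left in place — this bounds the work on
  near-saturated vertices while conserving the edge count exactly for
  every $q$. Redrawing may recreate the just-removed edge; with $n = 200$
  agents this inflates edge survival by $q/n \approx 0.25\%$, far below
  the Monte-Carlo noise of any statistic we track. `base = "torus"` gives
  the *modified* small-world family that rewires the Moore torus
  (441 agents at the default $21 \times 21$) instead of the ring.

Networks can also be loaded from plain two-column edge lists
(`read_edgelist()`), and exported to igraph or GraphML.

## Seeding and reproducibility

Every sweep derives one seed per replicate from the master seed, and each
replicate seed is split (again through R's RNG) into four sub-seeds: the
network draw, the type initialization, the action initialization, and the
flip stream. The replicate seed is recorded in the output table and
echoed in the run manifest, so any single row can be regenerated in
isolation. The compiled simulation core draws from R's own RNG in
increasing agent-id order, which makes the one-step R reference
implementation (`br_step()`) bit-identical to the compiled runner under
the same seed — a property the test suite exploits.

## Experiment protocol and problem sizes

The packaged experiment drivers follow the study design the defaults
describe:

* **Torus sweep** — the $41 \times 41$ torus (1681 agents), rebel ratio
  $r \in \{0, 0.05, \ldots, 1\}$ (21 values), updating probability
  $p \in \{0.05, 0.10, \ldots, 1\}$ (20 values), 10 replicates per
  combination, 500 steps per run: 4200 runs. Initial types are i.i.d.
  Bernoulli($r$), actions i.i.d. uniform. Satisfaction summaries are also
  reported on a 21 × 11 display subgrid with
  $p \in \{0.05, 0.1, 0.2, \ldots, 1\}$; the exact 11-value subset is a
  display convention and moves the grand mean by well under a point,
  because the index is insensitive to $p$ outside the high-$r$,
  high-$p$ corner.
* **Phase scan** — all-rebel torus, $p$ on a fine grid in $[0.8, 1]$,
  5000 steps and 10 replicates per point: the equilibrium ratio collapses
  from 1 to 0 inside $p \in [0.85, 0.90]$.
* **Small-world sweep** — rings of 200 agents, density
  $d \in \{8, 18, 28, 38, 48, 58\}$, rewiring $q$ and rebel ratio $r$ on
  11-value grids, $p \in \{0.1, \ldots, 1\}$, fresh network per
  replicate, 500 steps. The packaged acceptance protocol runs 3
  replicates per combination (21,780 runs) rather than 10; at this size
  the grand means carry binomial/CLT standard errors of well under one
  point, which the widened tolerances of the scaled protocol reflect.

At uniform random initialization the expected indices are available in
closed form (`expected_initial_indices()`): an agent of degree $d$ is
satisfied with probability $P(\mathrm{Bin}(d, 1/2) \ge \lceil d/2
\rceil)$ — $163/256 \approx 0.637$ at degree 8 — the expected
satisfaction degree is $1/2$, and the expected complete ratio is
$2^{-d}$, independent of the rebel ratio by symmetry.

## Lattice pattern statistics

On the torus, converged configurations organise into **continents** —
maximal connected same-action regions under the game's own (Moore)
adjacency, computed by `continents()`. For all-conformist states an agent
is completely satisfied iff she lies in the interior of her continent, so
`interior_fraction()` must equal the complete ratio exactly there; the
function refuses states containing rebels, where the equivalence fails.
All-rebel equilibria instead look like **mazes** of width-one streets: a
street agent has exactly two same-action neighbours (satisfaction 3/4),
which `street_fraction()` counts. The package reduces maze/strip/wheel
geometry to these quantitative statistics; shape classification and
rendering beyond `autoplot()` raster views are out of scope.

## Numerical and design choices

* Satisfaction thresholds are evaluated in integer arithmetic
  ($2L_i \ge d_i$), so no floating-point tie ambiguity exists.
* `enumerate_pure_equilibria()` is an exact oracle: it walks all $2^n$
  profiles (vectorised in chunks, refusing $n$ above a configurable cap)
  and returns equilibria in binary counting order, agent 0 as the least
  significant bit. It exists to validate the dynamic and the fixtures,
  not to scale.
* The deterministic cycle detector hashes visited profiles and reports
  the first recurrence; for an eventually-periodic deterministic map the
  first recurrence interval *is* the cycle length.
* Empty record sets raise errors rather than returning silent zeros
  (`equilibrium_ratio()`), and configuration errors are raised before any
  simulation starts, naming the offending field.

## What the tie rule does and does not reproduce

The tie convention deserves emphasis because it is the single most
consequential modelling choice. With ties satisfied (the model used
here), blocked configurations are identical under every activation
scheme — synchronous, stochastic, or sequential — and the dynamic on the
torus freezes into moderately coarse patterns: converged all-conformist
lattices show complete ratios around 0.55–0.6 and average satisfaction
near 0.87, all-rebel lattices converge to imperfect mazes with average
satisfaction near 0.64–0.67, and the synchronous phase transition sits
sharply inside $[0.85, 0.90]$. Variants in which indifferent agents also
move (with probability $p$ or $p/2$) coarsen much further — near-perfect
continents at $r = 0$ and street-dominated mazes at $r = 1$ — but they
lower the grand cooperation degree substantially and shift the all-rebel
phase transition down to roughly $p \in [0.5, 0.7]$, because absorption
then requires strict satisfaction everywhere. The two behaviours cannot
be combined in a single threshold rule; this package implements the
ties-satisfied rule throughout and reports whatever it produces.

## Limitations

The synthetic experiments emulate i.i.d. random type and action
initializations on exactly regular or WS-randomised networks. Real
social networks have heavy-tailed degrees, clustering, and homophily,
none of which the generators produce (scale-free and homophily-structured
variants, and co-evolving networks, are deliberately out of scope); a
passing suite shows the dynamic behaves as specified under the stated
conditions, not that the quantitative levels transfer to empirical
networks. Mixed-strategy equilibria are not simulated, and the
NP-hardness of deciding pure-equilibrium existence on general networks is
taken as given rather than re-derived — the enumeration oracle is
exponential by design and capped accordingly.
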