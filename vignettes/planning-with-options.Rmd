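---
title: "Model-based planning with options: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based planning with options: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltatory)
```

This vignette documents the models implemented by **saltatory**, the
parameters that matter, and the design choices made where the literature
leaves the details open. It is the companion to the function reference; no
empirical claim here goes beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The problem

A model-based (goal-directed) agent chooses by *planning*: simulating
candidate futures against an internal model instead of relying on cached
action values. Hierarchical reinforcement learning augments the primitive
action set with *options* — temporally extended subroutines with an
initiation set, an internal policy, a termination function, and a
pseudo-reward that defines their subgoal. An *option model* summarizes an
option by (i) a joint distribution over termination state and duration and
(ii) the expected cumulative discounted reward accrued during execution.
With option models, a planner can leap straight to predicted subgoal
outcomes ("saltatory" planning) instead of simulating every low-level step.

The package studies three agents in the classic four-room gridworld:

* **flat** — primitives only;
* **hierarchical** — primitives plus doorway options, executed step-by-step
  through the primitive model (no option models);
* **saltatory** — primitives plus option models.

## The rooms environment

Maps are ASCII (`#` wall, `.` floor, `S` start, `G` goal), 0-based
`(row, col)` coordinates with row 0 on top. The shipped default is a 13x13
grid with an 11x11 interior: four rooms, four mid-wall doorways, 104 free
cells, start `(1,1)` in the upper-left room and goal `(11,11)` deep in the
lower-right room. The published figure this layout emulates shows colors,
not coordinates, so the exact cells are a documented fixture choice. We
place the goal in the far corner rather than beside the east doorway (the
other classic variant) because the deep goal preserves the headline
contrast that hierarchical agents converge in fewer trials than flat ones;
with a goal adjacent to a doorway the flat agent's learning problem becomes
easy enough that the option-exploration overhead dominates instead (both
placements were examined; see "Known limitations").

Transitions are deterministic by default; `success_prob < 1` moves in one
of the other three directions with the residual probability (used by the
option-model machinery, not by the planners). Defaults: step reward −1
(step counts equal negated undiscounted returns), goal reward 0, discount
γ = 0.95 throughout.

## Options and option models

Doorways are detected structurally: a free cell with exactly two free
neighbours whose removal disconnects those neighbours within the radius-2
induced subgraph. (Global articulation points fail here: with four rooms in
a cycle, removing one doorway never disconnects the map.) Tree-shaped maps
(corridors) have no rooms; detection is disabled with a warning. Removing
the doorways splits the free-cell graph into rooms; each doorway then
yields one option per adjacent room, launchable from that room's cells and
its other doorways.

Option policies are the greedy policy of value iteration on the
pseudo-reward problem (+1 at the subgoal, the step cost elsewhere,
absorbing at the subgoal, restricted to the initiation region; greedy ties
broken by fixed action order so policies are deterministic). The
termination function is 1 at the subgoal and everywhere outside the
initiation set — options never wander. Pseudo-rewards are used only for
option-policy construction and never leak into the planner's real values.

Exact option models follow the deterministic policy (point mass on
(subgoal, shortest-path length); expected reward is the discounted
geometric sum). For stochastic worlds the model is computed by dynamic
programming on the absorbing chain, truncated when the unterminated tail
mass falls below 1e-9. The Monte-Carlo estimator (`estimate_option_model_mc`)
is its empirical counterpart and doubles as an independent cross-check; its
agreement is tested per outcome cell at three standard errors where the
normal approximation applies (expected count at least 5), with rarer
outcomes aggregated into a single tail bin — the per-cell criterion is
meaningless for cells whose expected count is a fraction of an observation.

## The planners

Planning is modelled as trajectory sampling: each trial simulates one
ε-greedy trajectory from start to goal against the agent's internal model,
improving the plan along the way. The reference configuration applies a
**full one-step Bellman backup at every visited state** over the actions
the agent's model can predict (for the saltatory agent this includes
options, via their models; the hierarchical agent backs an option up only
after executing it, from the observed duration, arrival state and
accumulated reward, discounted by γ^k). Values start at 0 — optimistic
under negative rewards — which drives systematic exploration; ε = 0.1;
greedy ties are broken uniformly at random; α (backup damping) defaults
to 1.

Single-sample temporal-difference updates (α = 0.25) were evaluated first
and rejected for the reference configuration: on the default map no agent's
greedy policy converges within 100 trials under them, and with α = 1
single-sample updates the flat agent converges *faster* than the
hierarchical ones — the opposite of the phenomenon of interest. Full
backups at visited states are what a model-based planner that already owns
the model would compute, and they reproduce the qualitative result:
hierarchical agents reach their first optimal trajectory in fewer trials
than the flat agent (paired across 100 seeded runs, p ≈ 2e-3 one-sided),
and converged flat and hierarchical planners walk exactly the BFS-minimal
path. α remains available for damped updates.

A trial is abandoned (not completed) when its *simulated actions* exceed
`step_cap` (default 10·|S|). Simulated actions are primitive steps for flat
and hierarchical agents and decisions for the saltatory agent — leaping is
precisely what makes a saltatory trial cheap.

**Trials versus effort.** In a deterministic world the saltatory and
non-saltatory hierarchical agents learn almost identically (they differ
only in how option values are refreshed), so their trials-to-convergence
are statistically indistinguishable. The saltatory advantage is elsewhere,
and the package measures both: simulated actions per trial (final-decile
mean decisions ≈ 13 versus ≈ 16 versus ≈ 22 for saltatory, hierarchical,
flat on the default map) and robustness under memory limits (below).

Exact oracles accompany the sample-based planners:
`smdp_value_iteration` (Bellman backups over primitives and option models;
adding doorway option models changes optimal values by < 1e-8, since option
values are achievable by the primitives they abstract), BFS shortest paths,
and `min_decision_count` (minimum independent choices when options count as
one decision — on the 7-action chain with its two shipped options: 2
decisions instead of 7).

## Planning under memory failure

The memory-limited protocol gives the agent probability `p_fail` (default
0.1) of losing its place before each *decision-bearing simulation step*,
terminating the trial immediately; learning applies only to the pre-failure
prefix, and an option interrupted mid-execution is never backed up. For
flat and hierarchical agents every simulated primitive step carries working
memory, so each draws a check; the saltatory agent holds one decision per
option launch and draws one check per decision. This granularity — the
mechanism by which option models confer robustness — is the package default
and can be overridden (`per_step_failure`), since the literature does not
state the granularity for the non-saltatory agent. Completion of an
n-decision trajectory then follows the geometric survival law
(1 − p_fail)^n, which the tests verify empirically on 10^4 trials.

For failed trials the `rollout_to_goal` counting rule records what the
agent *would have taken*: its current greedy policy is rolled out, without
learning, from the failure point to the goal (censored at the step cap).

The memory experiment's default horizon is 500 trials rather than 100:
truncated trials carry roughly a tenth of the learning signal, and the
published protocol fixes the number of simulation runs (100), the smoothing
window (10) and p_fail (0.1) but not the trial count. At that horizon on
the default map the saltatory agent completes ≈ 11% of trials against the
flat agent's ≈ 5% (higher in every block of ten runs), its smoothed
would-have-taken curve ends well below the flat agent's (roughly 15–22
simulated actions against 35–45, oracle minima 9 and 20), and the
non-saltatory hierarchical agent fails outright (completion ≈ 0, curve
near the cap): charged per primitive step, its options spend the working
memory budget that its planning needs.

## Successor-representation subgoal discovery

A reward-free explorer takes uniformly random actions (`latent learning`),
and the empirical state-to-state transition matrix under that uniform
policy feeds the successor representation M = (I − γ_sr T)^{-1}
(γ_sr = 0.95; closed-form solve, cross-checked against the truncated power
series to 1e-6). Rows of M are predictive representations; their structure
is analysed three ways:

* **Clustering** — Ward agglomerative clustering on Euclidean row
  distances, with k chosen to maximize mean silhouette width over
  candidates 2–8 (deterministic; k-means behind a flag with a fixed seed).
  On the default map the silhouette curve peaks at k = 4 and the clusters
  are the four rooms (adjusted Rand index ≥ 0.9 against room labels,
  doorways excluded).
* **Bottlenecks** — states with silhouette below 0.05 or in singleton
  clusters, returned by ascending silhouette. On the default map this is
  exactly the four doorways. When the clustering itself is uninformative
  (mean silhouette < 0.1, e.g. a fully connected graph) no bottlenecks are
  reported: boundaries require communities.
* **Embedding** — classical MDS of row distances, centred, orientation
  arbitrary. Two dimensions preserve distance ranks imperfectly (Spearman
  ρ ≈ 0.76 on the default map; ≈ 0.97 at ten dimensions) — adequate for
  visualization, not for quantitative distances.

The 15-vertex community graph (three communities of five, all vertices
degree 4) exercises the same machinery on a non-spatial domain: within- and
between-community SR distances separate strictly, and the SR dip statistic
along a random walk is always larger across community bridges than within
communities — a predictive code suffices to parse the sequence at
boundaries.

## What the simulations do and do not show

The gridworld generator produces exactly the study conditions: small
deterministic mazes with unambiguous room structure, a single goal, and
unit step costs. Passing tests therefore demonstrate the *mechanisms* —
decision-count reduction, SMDP backup correctness, geometric survival,
SR-based structure recovery — not robustness to perceptual noise,
stochastic dynamics at scale, non-grid topologies, or function
approximation, none of which the fixtures exercise. The planners further
assume the model is given and exact; model learning during planning is out
of scope (the latent-learning module estimates transitions for the SR
pipeline only).

## Numerical choices and degenerate inputs

Value iteration converges to sup-norm tolerance 1e-10 (1e-12 in oracle
comparisons) with a 5000-iteration cap; γ = 1 is admitted (absorbing goal).
Option-model rows must sum to 1 within 1e-9 and durations be positive —
violations are construction errors. Rollouts and trials censor at 10·|S|
simulated actions. Degenerate inputs fail loudly: non-rectangular maps,
missing or duplicated markers, unreachable cells (named in the error),
non-stochastic transition matrices, SRs with identical rows, walks from
isolated vertices. Random tie-breaking consumes RNG only when ties exist;
all experiment randomness flows through per-run seeds (`seed_base + run`),
making every experiment a pure function of its configuration.

## Known limitations

* Trials-to-first-optimal does not separate the saltatory from the
  non-saltatory hierarchical agent (see "Trials versus effort"); claims of
  a saltatory advantage should cite simulated actions or the
  memory-limited protocol instead.
* The published planner internals behind the figures this package emulates
  are not public; the reference configuration here is documented,
  self-consistent, and reproduces the qualitative contrasts, but it is not
  a curve-for-curve replication, and the goal-placement trade-off above is
  inherent: no single configuration we found yields *both* a strict
  hierarchical-over-flat and a strict saltatory-over-hierarchical
  trial-count ordering.
* Doorway detection assumes doorways are width-1 (exactly two free
  neighbours); wider passages are not detected as bottlenecks by the
  structural rule, though the SR pipeline may still isolate them.
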