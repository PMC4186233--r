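# saltatory

Hierarchical model-based planning with options in gridworlds.

Goal-directed agents plan by simulating candidate futures against an
internal model of the world. **saltatory** implements the computational
machinery for studying how *temporal abstraction* changes that process: it
augments a tabular model-based planner with *options* (temporally extended
actions with an initiation set I ⊆ S, an internal policy π<sub>o</sub>, a
termination function β, and a pseudo-reward defining their subgoal) and
with *option models* — for each launch state s, the joint distribution
P(s′, k | s) over termination state s′ and duration k, plus the expected
discounted reward R<sub>o</sub>(s) accrued during execution. Backups then
follow the semi-Markov form

&nbsp;&nbsp;&nbsp;&nbsp;Q(s, o) ← R<sub>o</sub>(s) + Σ<sub>s′,k</sub> γ<sup>k</sup> P(s′, k | s) V(s′),

so a *saltatory* planner leaps directly to predicted subgoal outcomes
instead of simulating each primitive step. The package provides:

* the rooms gridworld (ASCII maps, BFS/value-iteration oracles) and a
  15-vertex community graph for random-walk sequence studies;
* doorway-option construction (structural doorway detection, option
  policies by value iteration on the pseudo-reward problem) and option
  models, exact (absorbing-chain) and Monte-Carlo;
* three trajectory-sampling planners — flat, hierarchical (options without
  models, simulated step-by-step) and saltatory — with exact SMDP
  value-iteration and minimum-decision-count oracles;
* planning under memory failure: probability `p_fail` per decision-bearing
  simulation step of losing one's place, with the geometric survival law
  (1 − p_fail)<sup>n</sup> and "would-have-taken" counterfactual rollouts;
* successor-representation subgoal discovery: latent-learning transition
  estimates, M = (I − γT)<sup>−1</sup>, Ward clustering with
  silhouette-selected k, MDS embedding, and bottleneck (doorway)
  identification.

Results come back as tibbles with `tidy()`, `glance()` and `autoplot()`
methods; a thin CLI lives in `inst/cli/saltatory-cli`.

## Worked example

```r
library(saltatory)
w <- read_map(system.file("extdata", "rooms_default.map", package = "saltatory"))
w
#> <gridworld> 13x13, 104 free cells, start (1,1), goal (11,11)

opts <- make_doorway_options(w)
length(opts)                            # 4 doorways x 2 sides
#> [1] 8
shortest_path_length(w, w$start, w$goal)
#> [1] 20
min_decision_count(w, opts)             # options count as one decision
#> [1] 9

res <- run_planning(w, agents = c("flat", "hierarchical", "saltatory"),
                    n_trials = 100, n_runs = 20)
glance(res)
#> # A tibble: 3 x 7
#>   agent        n_runs n_trials completion_rate mean_final_steps mean_final_decisions
#> 1 flat             20      100            1                22.3                 22.3
#> 2 hierarchical     20      100            0.99             25.2                 16.7
#> 3 saltatory        20      100            1                23.4                 13.3
```

All three agents converge to 20-step paths (the small excess over 20 is
ε-greedy exploration), but the agents with options need far fewer
*decisions* per trial — 13.3 for the saltatory planner against 22.3 for
flat — because an option spanning many steps is a single independent
choice. The same asymmetry makes saltatory planning robust when each
decision-bearing simulation step risks losing one's place
(`run_planning(..., p_fail = 0.1)`, `experiment_memory_planning()`).

Subgoals fall out of predictive representations alone:

```r
sr <- successor_representation(uniform_walk_transitions(w), 0.95)
cl <- cluster_states(sr)
cl
#> <sr_clustering> ward, chosen k = 4 (mean silhouette 0.377)
free_cells(w)[identify_bottlenecks(sr, cl), ]
#> # A tibble: 4 x 3
#>   state   row   col
#> 1    79     9     6
#> 2    52     6     3
#> 3    26     3     6
#> 4    53     6     9
```

The four silhouette-selected clusters are the four rooms, and the
low-silhouette states are exactly the four doorways — bottleneck states,
natural subgoals, discovered without any reward.

See `vignettes/planning-with-options.Rmd` for the models, parameter
choices and design notes.

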