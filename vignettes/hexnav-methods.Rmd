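---
title: "Quantifying goal-directed maze navigation with hexnav"
author: "hexnav authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying goal-directed maze navigation with hexnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 4.5)
library(hexnav)
```

## The problem

Mice learning to localize a rewarded node (the goal location, GL) in the
HexMaze — a large modular arena of six hexagonal corridor modules around a
central hexagonal circuit — express a mixture of undirected exploration and
goal-directed running. Because the maze constrains movement to gangways
between 24 discrete intersections, a trial is fully described by the
sequence of visited nodes, and the analysis of navigation becomes graph
analysis. `hexnav` implements the complete pipeline: the maze graph and its
geodesics, trial statistics, a parametric description of within-trial
straying, a two-parameter generative model of navigation, and the
Kolmogorov–Smirnov (KS) machinery that fits the model to trial groups. A
synthetic-protocol generator makes every stage testable end to end with
known ground truth.

## The maze graph

```{r maze}
g <- build_hexmaze()
g
plot(g)
```

The graph is the unique tessellation compatible with the published
structure: 24 nodes and 30 gangways forming twelve two-way and twelve
three-way choice points, an inner ring (6-cycle of three-way nodes) and an
outer ring (18-cycle), with every internal face a hexagon. The physical
gangway length is 36.3 cm; all analysis distances are counted in edges, and
coordinates exist only for plotting. The published description does not
include a node numbering, so the package defines its own convention (inner
nodes 1–6 counter-clockwise, outer nodes 7–24 counter-clockwise starting at
the gangway leaving node 1); it is stable but not guaranteed identical to
the original.

Barriers are modelled purely as edge removals and must leave the maze
connected. Because start–goal pairs can admit several equal-length shortest
paths, the *optimal path set* — every node on any geodesic — is the
reference object for distance-from-path statistics. It is enumerated
exactly by the bidirectional BFS criterion `d(s,v) + d(v,t) = d(s,t)`
(`optimal_path_set_exact()`); the noisy-edge-weight procedure
(`optimal_path_set_noisy()`), which recovers the same set as the union of
shortest paths under small random weight perturbations, is retained as an
independent validation mode. The perturbation bound `noise_scale <
1/30` guarantees noise can never promote a non-geodesic: a geodesic's
perturbed weight is below `d + 1` while any longer path stays above it.

## Trial statistics

Two statistics carry the analysis:

* **RTL (relative trial length)** — edges traversed until the first goal
  arrival divided by the geodesic distance. Length is deliberately counted
  in *edges*, not visited nodes, so a geodesic trial scores exactly 1
  (log10 RTL = 0). Counting nodes would shift both numerator and
  denominator by one and make the optimum depend on distance.
* **DFOP (distance from optimal path)** — at every visited node, the graph
  distance to the nearest member of the optimal path set. Its per-step
  group average rises from 0 and falls back, the "bump" whose height and
  width summarize straying.

Supporting statistics: the maximal DFOP of a trial, the fraction of node
visits on the outer ring (the rings partition the maze, so inner and outer
fractions sum to one; occupancy is node-weighted because no time stamps
exist), visit counts of arbitrary nodes (`node_crossings()`), and the
probability of an "optimal trial" (RTL < 1.5). Uncertainty throughout is
the SD over 50 bootstrap resamples.

Trials are grouped per condition (build-up, location update, barrier
update) and session into the bins *first trial*, *2–11*, *12–21*, *22–31*;
trials beyond 31 are excluded.

DFOP profiles average trials of one group per step. Completed trials are
zero-padded after goal arrival up to the horizon (default: the 95th
percentile of the group's step counts): the goal lies on the optimal path,
so the distance-zero continuation is the natural extension and reproduces
the observed convergence to zero; padding can be disabled.

Goal-shuffle surrogates (`gl_shuffle()`) test whether a trend is
goal-specific: goals are permuted without replacement across the trials of
a block and the RTL is recomputed toward the surrogate goal on the
sub-trajectory up to its first visit, with a default RTL of 10 when the
surrogate goal is never visited. If a surrogate goal coincides with a
trial's start the ratio is undefined (0/0) and reported as `NA`; such
trials are rare and excluded.

## The difference-of-Gaussians parametrization

Group DFOP profiles are summarized by the three-parameter curve

$$ g(x) \;=\; A\,\frac{e^{-x^2/2L_1^2} - e^{-x^2/2L_2^2}}{Z},
\qquad L_1 > L_2 > 0, $$

where the Gaussians are *unit-amplitude*, not densities: the density
normalization `1/(L√2π)` would make the difference negative at the origin
whenever `L1 > L2`, contradicting a bump that rises from zero. `Z` is the
maximum of the bracketed difference over `x ≥ 0`, computed on a 0.01-step
grid over `[0, 3 L1]` (the analytic argmax lies well inside this range), so
that `g(0) = 0` and `max g = A` exactly. `A` is the peak stray in edges,
`L2` the ascending and `L1` the descending length scale in steps; the
"steps to reach the maximum" is the argmax of the fitted curve.

```{r dog}
prof <- data.frame(step = 0:30, mean = dog_curve(0:30, A = 2, L1 = 8, L2 = 2),
                   n = 50)
fit <- fit_dog(prof)
coef(fit)
plot(fit)
```

Fitting is bounded Levenberg–Marquardt least squares on the profile means,
with `L1 > L2` enforced by the parametrization `L1 = L2 + δ, δ > 0`, ten
random restarts drawn through the caller's RNG, and convergence tolerance
1e-8. A flat profile is returned as a degenerate fit (`A = 0`) rather than
an error. Published fits do not state whether profiles were pooled across
animals; `hexnav` fits pooled per-group profiles and leaves per-animal
fitting to the caller (the fitter accepts any profile data frame).

## The generative navigation model

The virtual mouse moves between adjacent nodes, never reversing (the
previous node is excluded from the choice; at the start all neighbors are
available). Two parameters govern departures from this memoryless search:

* **η** — at each step in search mode, with probability η the agent commits
  to a *diagonal run*: a shortest path to a uniformly chosen outer-ring
  node at distance ≥ 3, after which search resumes. Runs model the long
  sweeping excursions that carry an animal to another maze section.
* **F (foresight)** — on every node arrival a draw
  `x ~ Exponential(mean F)` is compared with the goal distance `d`; if
  `d < x` the agent runs a geodesic straight to the goal and the trial
  ends. The trigger probability is `exp(-d/F)`; `F = 0` never triggers, and
  very large `F` reproduces fully goal-directed behavior.

Interpretive choices, made once and kept: the foresight check runs on
*every* arrival, including the start node and during diagonal runs; a new
diagonal run cannot start while one is in progress; geodesics are sampled
uniformly among all shortest paths (next steps weighted by geodesic
counts); first arrival at the goal always ends the trial; and the
no-reversal rule also binds runs — a run whose only shortest path would
immediately re-enter the previous node is simply not started at that step.
Trials are censored at `max_steps` (default 5000, far above the maze
diameter of 7); censored runs are excluded from distribution comparisons
and their count reported. At η = 0, F = 0 censoring occurs in well under
0.1% of runs.

```{r sim}
set.seed(1)
t <- simulate_trial(g, start = 8, goal = 16, sim_params(eta = 0, foresight = 1))
t
relative_trial_length(t, g)
```

## Fitting the model: KS distance on RTL

For each `(η, F)` on a grid (defaults η ∈ {0, 0.02, …, 0.20},
F ∈ {0, 0.1, …, 4}; published best-fit foresight never exceeds 2, so the
grid allows a two-fold margin), the navigator simulates `n_reps` runs per
observed trial's start–goal pair, and the two-sample KS distance between
simulated and observed RTL distributions is the objective. Maximal DFOP and
outer-ring occupancy are *held out*: they are compared only at the selected
pair, as validation that a model fitted on trial length alone also captures
where the animal strayed and which ring it occupied. Simulated runs are
pooled across a group's trials, mirroring how observed distributions are
pooled.

**Model selection on a noisy, partly flat surface.** The KS surface is
estimated by Monte Carlo, and η moves the RTL distribution only weakly
(measured on large simulations: the true KS distance between η = 0 and
η = 0.2 at F = 1 is below 0.02, while one 0.1 step in F moves it by about
0.03). A raw argmin therefore wanders along the η axis. `fit_strategy()`
instead extends the parsimony tie-break to statistical ties: with the
tolerance `0.5·sqrt(1/n_obs + 1/n_sim)` (about two asymptotic SDs of the
two-sample KS statistic), it selects the smallest `F` whose profile minimum
over η is within the tolerance of the grid minimum, then the smallest η
within twice the tolerance of that profile minimum. The stricter η bar
reflects its weaker identifiability. The constants were calibrated on
synthetic ground-truth recovery: across F_true ∈ {0, 0.5, 1, 1.5, 2} with
η_true = 0 (75-trial cohorts, 50 runs per trial), 25 of 25 fits return
η = 0 with median F error ≤ 0.1, while a strong true η (0.2 at F = 0,
whose KS footprint is ≈ 0.04) is still detected as nonzero. Conversely the
conservative bar *underestimates* a true η, and at F ≳ 1 a moderate η is
genuinely invisible to RTL — a limitation inherent to the objective, not
the implementation.

Effective sample sizes follow the `n·m/(n+m) ≥ 50` rule: groups below it
are excluded from fitting, and the rule is enforced before significance
claims. Bootstrap uncertainty for the fitted parameters resamples the
*observed* trials with replacement and re-evaluates the KS surface against
the cached simulated samples (the model side is treated as fixed — it can
be made arbitrarily precise by `n_reps`, while the observed side carries
the sampling noise); each resample is pushed through the same selection
rule. `foresight_trajectory()` applies the fit per (condition, session,
bin) group, giving the learning curve of `F`; groups can be compared with
`ks_two_sample()` on their bootstrap foresight distributions (one of
several constructions consistent with the published "comparison of model
distributions"; the exact published construction is not specified).

## The synthetic-data generator

`generate_protocol()` reproduces the training constraints under which start
locations were drawn: starts do not repeat consecutively, lie at least two
choice points from each other and from the goal, at least 60% of a
session's trials admit a unique geodesic, and a session's first start
differs from the previous session's first and last. Goals are placed on the
inner ring with probability 1/4, the counterbalancing used across animals.
Generation is rejection sampling (bounded at 10⁴ attempts per session,
deterministic under seed); the 60% constraint has a per-session acceptance
probability near 10%, so generation is fast. "Two choice points distance"
is read as graph distance ≥ 2 edges. Barrier-update protocols remove 1–3
gangways chosen so the maze stays connected, every eligible start keeps
distance ≥ 2 to the goal, and at least half the eligible starts see their
geodesic set change — the published barrier positions are not given, so
positions are sampled under these functional constraints.

`generate_dataset()` drives the navigator with a per-(session, bin)
ground-truth schedule `(η, F)`. The packaged `learning_schedule()` rises
within and across sessions and saturates at F = 2, the ceiling observed for
fitted animal behavior; η stays 0, matching the finding that the random
component does not change with learning. What the generator emulates is the
*protocol shape and the generative model itself*; it does not emulate
wall-clock time, reward handling, olfactory cues, video tracking noise, or
any behavior outside the model class (e.g. wall-following, pausing,
systematic turning biases). Recovery tests on generated data therefore
demonstrate that the pipeline is correct and well calibrated, not that the
two-parameter model is a complete account of real mice.

## Numerical and design choices

* Geodesic counting uses BFS order accumulation; geodesic sampling weights
  next steps by downstream path counts, giving the uniform distribution
  over geodesics.
* The KS statistic is computed by `stats::ks.test` (asymptotic p-values;
  ties are inherent to discrete RTL values, so exact p-values are never
  requested); grid searches use an equivalent sorted ECDF sweep for speed,
  tested against `ks.test` on tied data.
* Degenerate inputs fail loudly and early: start = goal trials, censored
  trials in RTL, empty groups, disconnecting barrier sets, noise scales
  that could flip geodesics, schedules not covering a bin.
* Problem sizes in tests and the acceptance analysis: recovery experiments
  use 25-animal cohorts of first trials (75 pairs, 50 runs each, the
  published first-bin scale); the validation-match analysis uses a
  750-trial group (the published 2–11-bin scale); the random-walk baseline
  uses a 24-animal cohort in which every node serves once as a goal,
  removing goal-sampling variance while preserving the 1-in-4 inner-ring
  counterbalance.
* All randomness flows through R's RNG: a single `set.seed()` reproduces
  any simulation, protocol, fit or bootstrap bitwise.

## Known limitations

* η and F are close to confounded for RTL at moderate foresight; the
  parsimony rule makes the reported η conservative. Distinguishing them
  sharply would need the held-out statistics inside the objective, which
  the design deliberately avoids to keep them as validation.
* The maze numbering convention, though structurally equivalent, need not
  match the original experimental numbering, so node-level comparisons
  with external datasets require a relabeling map.
* Bootstrap refits hold the simulated samples fixed; the small additional
  Monte-Carlo variance of the model side is not propagated.
* DFOP profiles are per graph step, not per unit time; dwell times are
  outside the data model.
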