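---
title: "The Social Honesty game: model, dynamics and measurement choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Social Honesty game: model, dynamics and measurement choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The Social Honesty game is a two-strategy social dilemma played between
neighbors on an interaction graph. A player is *honest* (H) or
*dishonest* (D). Dishonesty is tempting — it pays an advantage `b` when it
goes unpunished — but the community (or an authority) detects and punishes
a dishonest act with probability `p`, and a punished player loses `s`
("severity"). Because detection is uncertain, payoffs are random
variables, not constants:

* **H–H**: both players earn the reward `R`, deterministically.
* **H–D**: the honest player earns 0; the dishonest one is punished
  (payoff `−s`) with probability `p_hd`, otherwise wins `b`.
* **D–D**: a fair coin decides which of the two wins `b` (the other gets
  0); each of them is then punished *independently* with probability
  `p_dd`, punishment overriding the coin outcome. The two can never win
  `b` simultaneously, but both can be punished.

Each unordered pair draws **one** realization per round, shared by both
participants: an interaction is a single joint transaction, so the two
sides must see a consistent outcome.

`sh_params()` bundles `R, b, s, p_hd, p_dd` with defaults `R = 1`,
`b = 3`, `s = 2` and a single shared `p` filling both punishment
probabilities (set `p_dd` separately to study regimes where dishonest
pairs are hard to expose).

### Choices behind the payoff law

Three aspects of the payoff law are genuinely open and are fixed here as
package-level decisions:

* **Normalization `R = 1`.** All other payoff scales (`b = 3`,
  `s ∈ {0, 1, 2, 4, 8}`) are interpreted relative to a unit honest
  reward. We probed `R = 0.5` during development: it shifts every
  transition to substantially higher punishment probabilities and
  eliminates stable mixed equilibria at severity 2, both at odds with the
  behavior the model is meant to exhibit, which supports the unit choice.
* **Punishment replaces the payoff (`−s`), it is not subtracted from
  `b`.** Severity enters as the standalone bad outcome of a two-point
  random variable. The choice is centralized in one sampling routine, so
  an additive variant is a one-line change.
* **D–D resolution order.** The coin picks the winner first; punishment
  draws then override individual payoffs. When nobody is punished this
  reduces exactly to the "one wins `b`, one gets 0" rule; when one or
  both are punished it preserves "both may be punished" and "never two
  `b`s". The cross term (unpunished loser next to a punished winner) is
  the minimal completion consistent with those constraints.

## Spatial form and update rules

Players occupy a `rows × cols` lattice with joint (toroidal) boundaries —
every cell has a full neighborhood, there are no edge effects. Supported
neighborhoods: Moore (Chebyshev distance ≤ `radius`), von Neumann
(Manhattan distance ≤ `radius`), well-mixed (complete graph) and
scale-free (Barabási–Albert preferential attachment mapped onto the
lattice cells by a seeded random permutation; the placement only matters
for rendering). The scale-free default `m = 4` targets a mean degree near
8 so comparisons against the Moore radius-1 lattice are degree-fair; the
attachment is non-spatial, as the lattice mapping carries no distance
constraint here.

A round consists of (1) every adjacent pair playing the game once and
each player summing its pair payoffs — raw sums, *not* degree-normalized,
which matters on heterogeneous-degree graphs — and (2) a **synchronous**
strategy revision:

* **best**: adopt the strategy of the highest-payoff member of
  self + neighbors. Ties: keep your own strategy if you attain the
  maximum, else pick uniformly among the maximal neighbors. Including
  self (with keep-own tie-breaking) is the standard spatial-EGT
  convention and keeps homogeneous states absorbing under ties; the
  comparison set is switchable (`include_self = FALSE`) for sensitivity
  runs, and excluding self does not qualitatively change the transition
  structure in our checks.
* **best-myopic**: with probability `q` (default 0.9) apply the best
  decision, otherwise copy a uniformly random neighbor's current
  strategy.
* **best-Fermi**: adopt the best neighbor's strategy with probability
  `1/(1 + exp((π_self − π_best)/K))`, else keep your own. `K` (default
  0.1) is the usual selection temperature; at `K → 0` this approaches the
  deterministic best rule, the default makes a payoff gap of 1 nearly
  decisive while leaving genuine noise at small gaps.

All randomness flows through R's global RNG; a run is bit-for-bit
reproducible from its master seed, which fans out to child seeds by a
counter-based derivation (`child_seed`) so enlarging a batch never
perturbs earlier replicates.

## What the dynamics look like

From a 50% random start at severity 2, honesty first collapses — isolated
honest players are exploited and imitate their successful dishonest
neighbors — and only compact honest clusters survive. Whether those
clusters then grow, coexist, or die depends on where `p` sits relative to
a narrow **transition interval**: below it dishonesty takes the whole
population in every replicate; above it honesty fixates in every
replicate; inside it the population settles into long-lived mixed states
whose level rises steeply with `p`. In this implementation the
severity-2 interval sits near `p ≈ (0.50, 0.53)` on a 100×100 Moore
radius-1 torus, and the minimum critical probability across severities
(attained at `s = 8`) measures ≈ 0.31 at pilot replication — punishment
certainty substitutes for severity, not the other way around.

One quantitative caveat is documented rather than hidden: at the midpoint
of the measured severity-2 interval the three-round collapse bottoms out
at roughly 16–28% honest, not at the few-percent level associated with
the regime where recovery follows a near-extinction. In this payoff
completion a collapse to ≈2% only occurs below the interval, where
honesty subsequently goes extinct; deep collapse and recovery do not
co-occur at the same `p`. The masked degrees of freedom in the payoff law
(the honest reward scale and the exact D–D cross term) are the most
plausible source of this offset, and the acceptance script reports the
measured value unadjusted.

## Measurements

* **Honest rate**: fraction of H cells; recorded after every round
  (entry 0 of a time series is the initial state).
* **Granularity**: `1 − mean_rows(adjacent within-row changes)/(cols−1)`,
  a row-scan statistic with no wrap-around and deliberately no column
  scan. It is 1 for a homogeneous state, 0 for a checkerboard, ≈0.5 for
  a uniformly random 50% mixture, and rises toward 1 when few large
  clusters dominate. It is invariant under H↔D relabeling and row
  permutations.
* **Sweeps and transition intervals**: for each parameter value the
  final-round honest rate of `n_runs` seeded replicates. The interval's
  lower bound is the largest value whose mean rate is ≤ `eps_low`
  (default 0.01 — "average dishonest domination" is not defined more
  precisely than that, so the threshold is explicit and configurable);
  the upper bound is the smallest value where **every** replicate
  fixates at 1 (a mean-threshold criterion is available as an option).
  A sentinel `-Inf` lower bound marks sweeps that dominate from the
  first grid value.
* **Critical probability**: the smallest `p` whose replicates all fixate
  honest by the final round, found by a coarse upward scan refined once
  at a fifth of the step — a compromise that keeps desk-scale runtimes
  while resolving the threshold to 0.001 at the default pilot step.
* **Evolved cluster states**: rather than painting clusters
  geometrically, clustered worlds are *grown*: a 50% random population
  evolves under a `p` chosen just above (for high honest targets) or
  just below (for low targets) the transition, and the first post-update
  state whose honest rate enters the target window is captured. The
  stopping rule checks after every round; trajectories that jump over a
  narrow window are simply re-seeded, which the harvesting helpers do
  automatically.
* **Plateau selection**: when asking "is there a stable mixed long-run
  plateau inside the interval, and at what level?", the scan classifies
  a scanned `p` as *stable mixed* if the across-replicate mean over
  rounds 300–400 lies in (0.05, 0.95) and drifts by less than 0.05
  between the window's ends, and reports the most-mixed such plateau
  (the one maximizing `min(level, 1 − level)`). The rule is fixed
  a priori; because the plateau level rises steeply across the narrow
  interval, the reported level is grid- and seed-sensitive at the ±10%
  scale.

## Synthetic initial states

`random_state()` places an *exact* count `round(h_fraction · n)` of
honest cells uniformly at random — exact-count rather than i.i.d.
placement, so "50%" is literal and small lattices carry no initial-rate
variance. `single_dissident_state()` puts one deviant in the middle of a
uniform field. These generators emulate the study conditions (random
mixtures at stated rates, single seeds, evolution-grown clustered
worlds); they do not emulate features of real social networks such as
degree–behavior correlations, community structure or noisy/asymmetric
punishment institutions, so passing tests demonstrate properties of the
model, not of any empirical population.

## Numerical and testing notes

* Homogeneous states are absorbing under every rule, so simulations exit
  early on fixation and pad the recorded series with the absorbed value;
  results are identical to running all rounds.
* Payoffs are small integers in exact double arithmetic; payoff ties are
  real events (not floating-point accidents) and the tie-breaking rules
  above are part of the model definition.
* Degenerate inputs are rejected by name (`p_hd out of [0,1]`, lattice
  too small for the radius, ragged grid files, etc.).
* Problem sizes in the test suite: the published-number checks run at
  100×100 with pilot replication (25 replicates for the critical
  probability on a bracketing grid, 20 replicates per scanned `p` for
  plateaus, 5–10 harvested states for granularity); structural
  properties use 6×6 to 30×30 lattices. The default suite and the
  acceptance script each complete in minutes on one CPU.

## Known limitations

* Strategy space is binary; no mutation/exploration noise, memory,
  reputation or identity — the dynamics are pure imitation.
* Synchronous updates only, as the model specifies.
* The scale-free construction is non-spatial preferential attachment;
  no small-world or dynamically rewiring topologies.
* Costly (altruistic) punishment — where punishers pay a fee — is out of
  scope: punishment here is an institutional event with probability `p`,
  not an individual's strategic act.
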