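---
title: "Modelling constrained propagation in spatio-temporal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling constrained propagation in spatio-temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnet)
```

## The model and its assumptions

`stnet` represents a system as a time-ordered sequence of `T` directed
snapshot graphs over one fixed node set, each snapshot covering a window
of `τ` seconds. Edges carry propagation speeds (length units per second);
an absent edge is speed 0 and an instantaneous one is `Inf`. Nodes occupy
positions in a metric space — k-dimensional Euclidean or the WGS-84
ellipsoid (Vincenty distances via `geosphere`) — and may move between
snapshots. Two modelling assumptions are enforced: every node exists in
every snapshot, and no two nodes share a coordinate within a snapshot
(`validateNetwork()` reports a violation as an error).

Interaction is a discrete-time spreading process. From an origin, progress
between a reached node `v` and an unreached node `w` accumulates by
`min(τ·S, max(0, D − P))` in each step where the edge is present, and
resets to zero when the edge disappears; `w` joins the reachability set
once accumulated progress covers the current pair distance. Three
semantic choices deserve emphasis, because the update rules alone do not
fix them:

* **One hop per timestep, even at infinite speed.** A node reached in step
  `i` can forward no earlier than step `i+1`, because arrivals are judged
  against the reachability set of the *previous* step. This caps cascades
  in contact networks at one hop per snapshot.
* **Progress freezing.** Once `w` is reached, all progress entries toward
  `w` stop updating. Reachability and path extraction never re-read them;
  freezing avoids assigning meaning to propagation toward an
  already-reached node.
* **Latency counts from the window start.** Waiting at the origin before
  the first usable edge is part of the temporal distance
  (`dist^λ = (arrival step − start step) · τ`), so origins on
  poorly-served schedules are genuinely "far" from everything.

A spatio-temporally shortest path minimises latency first and spatial
length (the sum of per-hop accumulated distances) second. Because the
per-hop distance is the progress value at arrival, it can exceed the
instantaneous straight-line distance when nodes approach each other; this
is accepted as the physically travelled distance. Shortest-path counting
follows the Brandes scheme on the per-origin predecessor DAG: every
predecessor achieving both optima at the arrival step is kept, and counts
sum along the DAG.

## Numerical choices

Arrival tests use a relative tolerance of `1e-9` (`P ≥ D − 1e-9·max(1, D)`)
so that exact-arithmetic constructions (e.g. three 50 km increments
covering 150 km) do not fail by one ulp; spatial-length ties use the same
relative tolerance. Ties between equal centrality scores in attack
orderings are broken by node identifier, making every deterministic curve
bit-reproducible. Distance matrices are cached per network when positions
are static.

The temporal granularity bound is checked as a *duration*: the minimum of
`D/S` over all snapshot edges with finite speed. If it is below `τ`, the
representation under-samples the dynamics and `validateNetwork()` warns.
(This bound is sometimes printed as the product `D·S`; a product of a
distance and a speed is not a duration, so the implementation uses the
dimensionally consistent quotient and says so in the warning text.)

## Components, efficiency and robustness

Temporal reachability is neither symmetric nor transitive: a node can
reach a hub whose return service has already ended. A strong component —
a set with spatio-temporal paths between *all* ordered pairs — therefore
cannot be read off the reachability digraph with a standard SCC pass.
`strongComponents()` instead builds the affine graph (an undirected edge
wherever both directions are reachable) and takes its maximal cliques;
the giant strong size `S` is the largest clique as a fraction of `N`. The
weak counterpart links pairs reachable in at least one direction.

Temporal efficiency averages reciprocal latencies in *timestep units*
over all ordered pairs, which pins it to `[0, 1]`: exactly 1 when every
ordered pair completes direct propagation in one step, 0 when nothing
propagates; unreachable pairs contribute 0. Spatial efficiency is the
literal mean reciprocal spatial distance (units 1/length). A normalisation
of spatial efficiency by straight-line distance ratios would also be
defensible and changes relative spatial robustness; the literal reading is
the default because it matches the definition of the temporal counterpart.

Deactivating a node removes its incident edges in every snapshot but keeps
`N` fixed, so efficiencies and `S` remain comparable across deactivation
fractions — a deactivated node depresses efficiency through its `2(N−1)`
vanished pair terms. Random error draws independent Bernoulli(`f`)
failures per node (expected `f·N` failures), the model under which `R(f)`
is an expectation; an `exactCount` flag removes exactly `⌈fN⌉` nodes
instead. Greedy re-ranking after each failure applies only to the
betweenness attacks (PB, BE); TC, ID, OD and PTPB rank once on the intact
network. Attack curves are recorded at every `k/N`; the area under a curve
is trapezoidal with constant extrapolation to `f = 0` and `f = 1`, a
convention recorded on the returned value.

For temporal in-closeness, the in-component of `v` is taken as the full
set of nodes with a path to `v` (plus `v`), which keeps the mean
in-distance well defined for every node; a singleton in-component gives
closeness 0. Betweenness conventions: pairs contribute only to interior
nodes, and for betweenness efficiency each source–destination pair counts
once no matter how many of its shortest paths cross the node. PTPB runs
the identical machinery on a derived network whose existing edges all have
infinite speed, with the spatial tie-break disabled so that *all*
minimum-latency paths are counted. Note that on a network whose speeds
are already infinite PTPB need not equal PB: PB still applies the spatial
tie-break among equal-latency routes, PTPB deliberately does not. They
coincide whenever minimum-latency routes are unique.

## Descriptive statistics

The topological temporal correlation is the per-node cosine overlap of
out-neighbourhoods in consecutive snapshots, averaged over the nodes for
which it is defined (0/0 terms skipped) and then over the `T − 1` snapshot
pairs; identical snapshots give exactly 1. Topological reciprocity is the
per-snapshot fraction of directed edges whose reverse coexists; weight
reciprocity is `Σ min(S_vw, S_wv) / Σ max(S_vw, S_wv)` over active dyads.
Both average over non-empty snapshots. For the weight ratio, infinite
speeds are capped at twice the largest finite speed (1 if none), so fully
instantaneous dyads count as reciprocated rather than producing `∞/∞`.
The radius of gyration is the RMS displacement of a trajectory about its
centroid, computed in a local equirectangular projection for geodesic
coordinates; stationary nodes give exactly 0. These definitions follow
the standard mobility/temporal-network literature and are pluggable
should a different convention be required.

## What the generators emulate

* `twoCityFixture()` / `fiveNodeFixture()` — deterministic worked examples
  (a 150 km / 200 km·h⁻¹ / 15 min rail link; a five-node plane with
  partial progress, an intermittent edge that twice loses its progress,
  and a three-hop route of 5 s and 4 m). The five-node geometry is locked
  by tests asserting those outcomes.
* `equalPBDiffBEFixture()` — two disjoint three-node chains whose middle
  nodes carry one source–target pair each (equal PB) at different speeds
  (BE 0.25 vs 0.5): the minimal dissociation of structural load from
  temporal value.
* `randomGeometricSTN()` — flight-like sparse systems: uniform points,
  distance-limited candidate edges, Bernoulli per-snapshot activation,
  log-normal speeds drawn once per directed edge. Default speeds centre
  direct propagation of a radius-length edge on two timesteps.
* `scheduledLinesSTN()` — transit timetables: lines sharing a hub (or a
  ring), bidirectional consecutive-station edges active during service
  steps, per-line speeds calibrated to `hopSteps` timesteps per hop, with
  optional slowdown jitter (slowdowns only, so the granularity bound stays
  satisfied) and per-record reliability. Service gaps emulate night
  closures.
* `connectomeSTN()` — static-topology neural wiring: identical snapshots
  (temporal correlation exactly 1), 2-D embedding at millimetre scale,
  edge classes (chemical/electrical/both) with speeds set so every direct
  delay `D/S` lies in a configurable 10–30 ms range, `τ` = 10 ms.
* `contactSTN()` — communication logs: intermittent bidirectional
  infinite-speed contacts, optional Gaussian random-walk mobility.

These generators reproduce the *mechanisms* of the real network classes
(periodic finite-speed edges, sparse long-range links, speed classes on a
fixed topology, instantaneous intermittent contact) but not their
empirical degree distributions, spatial layouts, or traffic rhythms; a
passing test suite demonstrates correctness of the algorithms under these
mechanisms, not conclusions about any particular real system.

## Validation scale and limitations

The engine is cross-validated against an exhaustive enumerator that
simulates every distinct-node sequence directly from the update rules and
accepts a sequence as a process trace only when each prefix arrives at its
endpoint's earliest arrival (the enumeration computes those earliest
arrivals itself). Agreement is exact — latencies, spatial distances,
reachability, path counts, PB and BE — on 200 seeded random instances
with up to 7 nodes and 10 snapshots, plus the infinite-speed variant.
Robustness behaviour is exercised on ensembles of 20 scheduled-lines
systems of 41 stations (24 snapshots), with 200-realization random-error
baselines; these sizes keep the complete suite within a few minutes on a
single core while leaving all code paths dense.

Known limitations: shortest-path trees cost `O(N²)` per origin per window
so all-pairs analyses scale as `O(T·N³)` worst case, comfortable to a few
hundred nodes; continuous-time event semantics and multi-hop-within-a-step
cascades are out of scope by design; the maximal-clique component
computation is exponential in the worst case, though mutual-reachability
graphs of the systems modelled here are small and dense enough that it is
not a practical constraint; edge-level failures, geographically localised
attacks and recovery dynamics are not modelled.
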