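---
title: "Tracking communities through dynamic networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking communities through dynamic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempcomm)
```

`tempcomm` detects community structure in a dynamic network — an ordered
series of two or more snapshots over a shared node universe — in two
stages: independent per-snapshot partitioning, then stitching and
trajectory assignment. This vignette explains the models, the parameters
that matter, the numerical and design choices made where the problem is
genuinely underdetermined, and what the synthetic benchmarks do and do not
demonstrate.

## Stage 1: groups

A *group* is a module of one snapshot; it exists only at its own time
point. Groups are found by Louvain modularity optimisation, implemented
directly in the package: repeated greedy local moves (each node tentatively
joins the neighbouring community with the largest modularity gain)
followed by aggregation of communities into super-nodes, until no move
improves Q. Three choices make the optimiser deterministic and therefore
make everything downstream testable:

* the node-visit order at every level is drawn from a private RNG stream
  seeded by the user's `seed`, over the *sorted* vertex names — so the
  result depends on the seed, never on the order in which the input file
  listed nodes or edges;
* a move is made only when it *strictly* improves Q (gain tolerance
  `1e-12`); an exact tie keeps the node in its current community, which
  minimises churn;
* ties among equally good target communities go to the lowest community
  id.

Edge weights are honoured throughout (weighted modularity); the resolution
parameter is fixed at 1, i.e. plain Newman–Girvan modularity. Isolated
present nodes form singleton groups — modularity offers them nothing to
gain by merging — and a snapshot with no edges at all yields all-singleton
groups with modularity reported as `NA`, since Q is undefined at zero
total weight. Louvain is a heuristic: the test suite verifies that it
attains the exhaustive optimum on all the small graphs used there, but on
large graphs it guarantees only a local optimum.

## Stage 1: communities

A *community* is a dynamic module persisting across snapshots. The groups
of the first snapshot become communities 1..G1. For each later time `t`,
every group seeks a match among earlier groups by Jaccard index, one
earlier time point at a time, starting at `t−1`:

1. at the earlier time point under consideration, all pairs (current
   group, earlier group) with `J ≥ θ` and `J > 0` are ranked by descending
   `J`, ties broken by lower current group id, then lower earlier group
   id;
2. pairs are accepted greedily, one-to-one in the earlier groups: no two
   current groups may claim the same earlier group at the same time point;
3. groups still unmatched continue to the next earlier time point, up to
   `search_depth` steps back (default: unlimited, i.e. back to the first
   snapshot);
4. groups unmatched after the whole search found new communities, numbered
   in (time, group id) order.

Several of these rules resolve genuine ambiguities and deserve comment.
The one-to-one rule exists because without it two groups at the same time
could both inherit one earlier community, and the per-time community
structure would stop being a partition — the table reports assume it is.
The `J > 0` floor means a "most similar group" must actually overlap the
group it passes its identity to, even at `θ = 0`. The search is
recency-first (first earlier time point containing *any* acceptable match
for that group, maximal `J` within it) rather than globally `J`-maximal
over all earlier times: community identity should flow through the most
recent occurrence of a module, since the snapshots are meaningful only in
their natural order. For the same reason the whole construction is
order-dependent by design: analysing the snapshots in a different order
produces different (and meaningless) communities.

Raising `θ` makes matches rarer, so communities fragment: more and smaller
communities, and more apparent node movement. `sweep_thresholds()`
quantifies this; stage 1 partitioning is threshold-independent, so sweeps
partition once and re-match per threshold.

## Stage 2, option A: the cost model

When communities can be assumed stable, each node is assigned a *home*
community trajectory `h_1..h_T` minimising

\[
\sum_{t\ge2} s\,[h_t \ne h_{t-1}] \;+\; \sum_t v\,[\text{present},\,
m(n,t) \ne h_t] \;+\; \sum_t a\,[\text{absent},\, h_t\ \text{present}]
\]

with switch cost `s`, visit cost `v` and absence cost `a`, all defaulting
to 1 and scale-free (scaling all three by λ scales every node cost by λ
and leaves the optimal trajectories unchanged). A node absent while its
home community is itself absent incurs nothing — a node cannot be expected
to attend a meeting that is not taking place. A switch and a visit can
co-occur at one time step; the two indicators are independent.

The minimisation is an exact dynamic programme over (time, candidate
home), independent per node. Two implementation choices matter:

* **Candidate homes** are restricted to the communities the node is ever
  observed in. A home never visited is weakly dominated: it can only ever
  collect visit and absence costs that some observed community also
  collects or beats. The tests pin this by comparing against exhaustive
  enumeration over the *unrestricted* candidate set.
* **Tie-breaking.** Many instances have several optimal trajectories. The
  DP minimises (cost, number of switches) lexicographically and then
  prefers the community the node was observed in earliest (then the lower
  id) at every decision, so the reported trajectory is canonical: a node
  that can stay loyal to one community at no extra cost will be reported
  with that single home.

The aggregate statistic `C/(N·T)` — total cost per node per time step,
`average_cost()` — diagnoses whether the stability assumption was
warranted; values near zero mean loyal nodes and persistent communities,
larger values mean the cost model is being forced onto unstable data and
the sub-community model is the better description.

## Stage 2, option B: the sub-community model

Here no cost is charged: each node takes its group's community at every
time point, and nodes are grouped by *exact* equality of their full
trajectory vectors. Labels follow three rules: a trajectory that never
changes over the times the node is present keeps the original community as
its label (this includes constant-but-partially-absent patterns such as
`(1, –, 1)` — no change is ever observed); a non-constant trajectory
shared by at least two nodes founds a new sub-community, with ids issued
above the community range in order of the first member's node id; a unique
non-constant trajectory is left unassigned. Absence participates in
pattern equality: two nodes share a sub-community only if they are also
absent at the same times, since "same dynamic behaviour" includes presence
dynamics. The "original community" reported for a node whose membership
varies is its first observed community.

*Node promiscuity* is reported as the number of consecutive time-point
pairs at which the node is present at both times with different
communities, divided by `T − 1`. The normalisation makes it comparable
across nodes and bounded in `[0, 1]`; transitions into or out of absence
are not community changes and do not count. (A raw change count is the
same quantity times `T − 1`.)

## The synthetic benchmark generator

`synthetic_dynamic_network()` draws a planted-partition (stochastic block
model) snapshot series: every node has a base community, a *cohort* is a
disjoint node subset that follows a prescribed sequence of target
communities in lockstep (a planted sub-community), edges appear
independently with probability `p_in` within the effective blocks and
`p_out < p_in` between them, and dropout removes a node from a snapshot
entirely — vertex and incident edges — with probability `p_absent`,
matching the absence semantics of the models. The generator returns the
planted membership matrix and cohort labels, and
`evaluate_recovery()` scores inferred against planted membership as the
adjusted Rand index per time point, averaged.

The benchmark regimes used in the tests are chosen to separate the two
stage-2 models: near-block-diagonal snapshots (`p_in = 0.95`,
`p_out = 0.02`, 4 communities × 12 nodes, T = 5) where partitioning and
matching should be exact and every planted cohort must come back as
exactly one sub-community; and noisier, dropout-laden regimes for the
threshold sweep trends. These sizes keep the full suite under a minute
while still exercising every code path; they are comfortable regimes for
Louvain, and passing them shows the machinery is correct, not that the
method is robust on hard real data. What the generator deliberately does
not emulate: realistic degree distributions, overlapping communities,
gradual membership drift (cohorts move in lockstep), or correlated noise
between snapshots.

## Input formats and discretisation

Dynamic GEXF files carry element lifetimes as spells, `start`/`end`
attributes or timestamps over continuous time, and nothing in the format
dictates how to discretise them into analysed snapshots. The package's
rule: observation times are the sorted distinct start values (and
timestamps); a spell `[start, end)` is closed on the left and open on the
right, so an element whose spell ends at an observation time is *not* in
that snapshot; an element with no lifetime information in a dynamic file
is present throughout. This is a documented convention, not a property of
the data — when it does not fit, the per-snapshot edge-list reader
(`read_edge_lists()`), where each file simply *is* one snapshot, is the
escape hatch. Self-loops are rejected at load time and edge weights must
be finite and positive; endpoints of an alive edge are always placed in
the snapshot.

## Degenerate inputs and numerical details

Floating-point comparisons in the Louvain gain test and the DP use an
absolute tolerance of `1e-12`; Jaccard values are exact rationals computed
from set sizes, compared with `>=` against the threshold. A node never
observed in any group has no candidate home and is reported as an error by
the cost model rather than silently assigned. Two empty node sets have no
defined Jaccard index (error); a zero-weight graph has no defined
modularity (error). Reports are deterministic: community colours are a
fixed function of the community id, CSV output is byte-identical across
reruns, and the HTML and CSV tables carry identical membership content.

## Limitations

Louvain is a local heuristic with a resolution limit; communities smaller
than the natural modularity scale can be absorbed. Identity stitching is
greedy and order-dependent by design and does not revisit earlier
assignments. Sub-community grouping is exact-match only: a single
dropped-out snapshot makes an otherwise loyal cohort member's pattern
unique (the worked example in the README shows exactly this), which is
the honest reading of "same dynamic behaviour" but can understate cohort
sizes under heavy dropout; tolerant (e.g. Hamming-distance) grouping is
deliberately out of scope. The cost model treats nodes independently;
there is no notion of community-level cost.
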