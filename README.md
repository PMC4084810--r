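# tempcomm

Community detection and tracking in dynamic networks.

Many systems — protein interaction networks sampled along a time course,
social groups observed event by event — are not static graphs but ordered
series of snapshots. Communities detected independently in each snapshot
carry no identity over time: group 2 at time 3 has no a-priori relation to
group 2 at time 4. `tempcomm` provides the two-stage procedure that makes
per-snapshot modules comparable across time, for analysts who have a
dynamic network and want to know which modules persist, which nodes are
loyal to them, and which sets of nodes move together.

## The method

**Stage 1 — groups and communities.** Each snapshot is partitioned
independently into *groups* by Louvain optimisation of the Newman–Girvan
modularity

```
Q = Σ_c [ w_in(c)/W − (d(c)/(2W))² ]
```

(`W` total edge weight, `w_in(c)` weight inside group `c`, `d(c)` the
summed degrees of its members). The groups of the first snapshot seed the
*communities*. Each later group is compared with the groups at earlier
time points by the Jaccard index `J(A,B) = |A∩B| / |A∪B|`, most recent
time point first, and inherits the community identifier of its best match
with `J ≥ θ` (threshold `θ`, default 0.4; matching within a time point is
one-to-one, greedy by descending `J`). A group with no acceptable match
anywhere within the look-back window founds a new community.

**Stage 2 — node trajectories.** Two alternative models:

* **Cost model** (communities assumed stable): each node gets a "home"
  community trajectory `h_1..h_T` minimising

  ```
  Σ_t≥2 s·[h_t ≠ h_{t−1}]  +  Σ_t v·[present, member of ≠ h_t]
                           +  Σ_t a·[absent, h_t present]
  ```

  with switch, visit and absence costs `s, v, a` (default 1 each), solved
  exactly per node by dynamic programming. Absence while the home
  community is itself absent costs nothing. The summary statistic
  `C/(N·T)` (total cost per node per time step) measures how stable the
  community structure actually is.

* **Sub-community model** (no stability assumed): each node simply takes
  its group's community at every time, and nodes whose entire membership
  trajectories — absences included — are identical form *sub-communities*.
  Constant trajectories keep their original community; unique non-constant
  trajectories stay unassigned. *Node promiscuity* (fraction of
  consecutive present-present time pairs with a community change) measures
  per-node volatility.

## Worked example

```r
library(tempcomm)

# a planted benchmark: 3 communities of 8 nodes over 5 snapshots, one
# 3-node cohort moving 1→2→3→1→2 in lockstep, 10% random node dropout
sim <- synthetic_dynamic_network(
  n_communities = 3, nodes_per_community = 8, n_times = 5,
  p_in = 0.9, p_out = 0.05,
  cohorts = list(list(nodes = 1:3, targets = c(1, 2, 3, 1, 2))),
  p_absent = 0.1, seed = 7)

fit <- track_communities(sim$network, model = "subcommunity", seed = 7)
summary(fit)
#> Two-stage dynamic community fit (subcommunity model)
#>   nodes: 24, time points: 5
#>   groups per snapshot: 3, 3, 3, 3, 3
#>   modularity per snapshot: 0.627, 0.498, 0.459, 0.578, 0.391
#>   communities: 3 (sizes 8, 11, 11)
#>   sub-communities: 1; unassigned nodes: 1
#>   mean node promiscuity: 0.1042
```

The three planted communities are recovered
(`evaluate_recovery(fit$timeline$membership, sim$membership)` returns 1,
the maximal mean adjusted Rand index). Two of the three cohort members
were present at all five times and share an identical trajectory, so they
form the one sub-community; the third dropped out at one snapshot, which
makes its pattern unique (absences count), so it is reported unassigned.

The cost model on the same network:

```r
track_communities(sim$network, model = "cost", seed = 7)
#> Two-stage dynamic community fit (cost model)
#>   24 nodes, 5 snapshots; 3 communities (Jaccard threshold 0.4)
#>   total cost C = 18; average cost C/(N*T) = 0.15
```

and a threshold sweep (partitioning is done once, matching re-run):

```r
sweep_thresholds(sim$network, thresholds = c(0.2, 0.4, 0.6), seed = 7)
#>   threshold n_communities mean_community_size n_subcommunities mean_subcommunity_size mean_promiscuity
#> 1       0.2             3                10.0                1                      2        0.1041667
#> 2       0.4             3                10.0                1                      2        0.1041667
#> 3       0.6             5                 8.4                3                      3        0.1979167
```

Stricter matching fragments communities (more, smaller communities) and
raises promiscuity, while the sub-community structure stays compact.

Reports: `write_membership_csv(fit$assignment, "membership.csv")` and
`write_html_report(fit$assignment, sim$network, "report.html")` render the
per-node, per-time tables (communities colour-coded; absences as dashes;
cost-model cells show home and visited community side by side).

## Command line

A thin Rscript wrapper drives the whole pipeline on dynamic GEXF files or
per-snapshot edge lists:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tempcomm-cli.R", package = "tempcomm"))')
Rscript "$CLI" run   --format edgelist --model subcommunity --out-dir out/ t1.txt t2.txt t3.txt
Rscript "$CLI" sweep --thresholds 0.2,0.4,0.6 --out-dir out/ t1.txt t2.txt t3.txt
```

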