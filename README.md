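# misinfluence

Centrality metrics and intervention simulation for health-misinformation
networks.

## The problem

During health crises, false claims travel through online social networks
faster than their corrections. Deciding **which accounts to prioritise** —
for fact-check queues, media-literacy prompts, or deplatforming — is a
network question: an account's danger depends on its position in the
directed interaction graph (who retweets whom), on its audience's
susceptibility, and on how its reach compounds over time. Classical
centrality captures static structural prominence but misses the last two
dimensions.

`misinfluence` is for researchers and trust-and-safety analysts working
with directed, weighted interaction graphs (edge lists of
`source,target[,weight]` rows plus optional per-node attribute tables). It
pairs the four classical baselines with three propagation-aware scores and
the framework needed to compare them and act on them.

## The metrics

With `G = (V, E)` directed, `n = |V|`, `N_in(v)` the in-neighbours of `v`:

* **Propagation centrality (PC)** — the fixed point of

  `x(v) = (1 − d)/n + d · Σ_{u ∈ N_in(v)} x(u) / d_out(u)`,  `d = 0.85`,

  a damped, out-degree-normalised steady state in the PageRank family:
  influence accumulates recursively, ranking accounts by long-range
  cascade potential.

* **Misinformation vulnerability centrality (MVC)** — each node starts
  with a susceptibility `vul_0(v) ∈ [0, 1]` (from attributes, observable
  feature columns, or a seeded uniform draw) amplified by exposure:

  `vul_{t+1}(v) = degree(v) × vul_t(v)`  (in-degree by default),

  run for 5 steps and min–max normalised: high scores mean *well connected
  and credulous*.

* **Dynamic influence centrality (DIC)** — cumulative influence from the
  all-ones start, `DIC_{t+1}(v) = DIC_t(v) + Σ_{u ∈ N_in(v)} DIC_t(u)`
  (equivalently `(I + Aᵀ)ᵗ·1`), run for 10 steps and normalised; its
  per-step trajectory feeds a **persistence profile** that surfaces
  "long-tail" spreaders who stay prominent across snapshots.

* **Baselines** — degree (in/out/total), closeness with an automatic
  harmonic fallback on fragmented graphs, directed betweenness (raw
  Brandes sums), and eigenvector centrality via teleport-perturbed power
  iteration justified by the Perron–Frobenius theorem.

Around the metrics: top-k overlap partitioning and coverage-gain
arithmetic, proxy-ground-truth rank alignment (Spearman with midranks),
an independent-cascade node-removal simulator with common random numbers,
and a seeded synthetic-network generator with planted, manifest-recorded
ground truth (hubs, vulnerable amplifiers, persistent spreaders). See
`vignettes/misinfluence-methods.Rmd` for models, assumptions and numerics.

## Worked example

Partition the four traditional top-10 influencer lists of the COVID-19
case study rebuilt by `rebuild_printed_toplists()`:

```r
library(misinfluence)
tl <- rebuild_printed_toplists()
overlap_partition(tl[c("degree", "eigenvector", "betweenness", "closeness")])
#> <top_k_comparison> 4 lists, union 29 nodes
#>   betweenness-exclusive                          2  1371, 2
#>   closeness-exclusive                           10  14, 28, 4, 42, 43, 5, 6, 62, 66, 83
#>   degree & eigenvector                           1  11248
#>   degree & eigenvector & betweenness             2  26, 756
#>   degree-exclusive                               7  11019, 142153, 33091, 40327, 64409, 83247, 84148
#>   eigenvector & betweenness                      6  102, 15, 235, 522, 526, 93
#>   eigenvector-exclusive                          1  593
```

The four lists name 29 distinct accounts, only two of which (`26`, `756`)
are shared by degree, eigenvector and betweenness at once — the metrics
largely disagree, which is the motivation for combining families.

Generate a synthetic retweet graph with five planted hubs, recover them
with PC, and measure a removal intervention:

```r
g  <- generate_network(synthetic_spec(n = 500, planted_hubs = 5, seed = 1))
pc <- propagation_centrality(g$network, pc_params(max_iter = 300))$scores
top_k(pc, 5)
#> [1] "n0372" "n0448" "n0002" "n0217" "n0181"
g$manifest$planted_hubs
#> [1] "n0133" "n0181" "n0217" "n0372" "n0448"

seeds <- g$attributes$node_id[g$attributes$misinfo_seed]
cfg   <- cascade_config(seeds, p = 0.1, runs = 1000, seed = 7)
evaluate_intervention(g$network, cfg, top_k(pc, 10), "pc-top10")
#> <intervention_outcome> pc-top10: 51.50 -> 43.28 spread (15.9% reduction)
```

Four of the five planted hubs sit in PC's top-5 (the fifth is displaced by
a naturally grown core node). Removing PC's top-10 cuts the mean
independent-cascade spread from 51.5 to 43.3 activated accounts — a 15.9%
reduction, measured with the same random draws in both arms so the
difference is not Monte-Carlo noise.

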