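---
title: "Propagation-aware centrality for health-misinformation networks: models and methods"
author: "misinfluence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation-aware centrality for health-misinformation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misinfluence)
```

## The problem

During health crises, false claims spread through online social networks
faster than corrections. Identifying *which accounts to prioritise* -- for
fact-checking queues, media-literacy prompts, or deplatforming -- is a
network problem: a user's danger is a function of their position in the
directed interaction graph (who retweets whom), their audience's
susceptibility, and how their reach compounds over time.

Classical centrality (degree, closeness, betweenness, eigenvector) captures
static structural prominence. This package pairs those baselines with three
propagation-aware scores -- propagation centrality (PC), misinformation
vulnerability centrality (MVC), and dynamic influence centrality (DIC) --
and the framework needed to compare them: top-k overlap partitioning,
coverage-gain arithmetic, proxy-ground-truth rank alignment, and a cascade
simulator for node-removal interventions. Everything is exercisable on
seeded synthetic networks with planted ground truth, so no external social
media data is required.

## The network model

A network is a directed graph $G = (V, E)$ with opaque string node ids and
strictly positive edge weights $w_{ij}$ representing interaction strength
or frequency; the adjacency view has $a_{ij} = w_{ij}$. Because weights
count interactions, duplicate $(i, j)$ rows in an edge list are summed, not
overwritten. Self-loops are dropped by default (and counted in the load
report): a user retweeting themselves carries no propagation information in
these models. Identifier fields are stripped of internal whitespace so
dataset dialects that typeset grouped digits ("11 019") load as one id.

All rankings in the package use one deterministic tie rule: descending
score, then ascending node id in the C locale. Top-k lists are therefore
reproducible across platforms, which matters because most of the
comparison framework consumes top-k lists.

## Classical baselines

**Degree** is the raw count of (merged) incident edges, split into in-,
out- and total on the directed graph.

**Closeness** is $C_C(v) = 1 / \sum_{u \ne v} d(v, u)$, defined only when
$v$ reaches every other node. Misinformation graphs are routinely
fragmented, so the harmonic form $H(v) = \sum_{u \ne v} 1 / d(v, u)$ (with
unreachable terms contributing zero) is provided, and `formulation =
"auto"` picks standard only when every ordered pair is reachable, recording
its choice in the result's parameters. Distances are hop counts by
default; in weighted mode an edge of weight $w$ has length $1/w$, because
strong ties transmit *faster*, not slower.

**Betweenness** is the raw sum over ordered pairs
$C_B(v) = \sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}$ with
endpoints excluded. Ordered pairs are the natural reading on a directed
retweet graph. The computation delegates to the Brandes algorithm (igraph);
the test suite pins it to an exhaustive simple-path enumeration oracle on
small digraphs.

**Eigenvector centrality** is computed by power iteration on
$M = A^\top + \varepsilon J$: the transpose because incoming links confer
status (consistent with PC's in-neighbour orientation; an out-link mode is
available), plus a uniform teleport perturbation $\varepsilon J$
(default $\varepsilon = 10^{-6}$) that makes $M$ strictly positive so the
Perron--Frobenius theorem guarantees a unique positive dominant
eigenvector even on fragmented graphs. One numerical subtlety: plain power
iteration never converges on periodic structures (an isolated reciprocal
pair has eigenvalues $\pm 1$; a $k$-cycle has $k$ eigenvalues of equal
modulus) because iterates rotate forever. The implementation therefore
iterates the shifted operator $I + M$, which has the same eigenvectors but
strictly separates the Perron root from every other eigenvalue of equal
modulus. The reported dominant eigenvalue is recovered by subtracting the
shift.

## Propagation centrality

PC is the fixed point of

$$x(v) = \frac{1 - d}{n} + d \sum_{u \in N_{in}(v)} \frac{x(u)}{d_{out}(u)}$$

iterated from the uniform vector $1/n$, with damping $d = 0.85$ by
default. Each node shares its influence equally among its out-neighbours;
influence accumulates recursively, so a node fed by influential accounts
becomes influential itself, and the steady state ranks accounts by
long-range cascade potential rather than raw connectivity.

Two design points the fixed-point equation leaves open:

* **Dangling nodes** (zero out-degree) contribute nothing under the
  literal reading of the equation, so total mass can drop below one. The
  default keeps the literal behaviour; `dangling_mode = "redistribute"`
  spreads dangling mass uniformly, restoring a stochastic iteration for
  comparability with conventional damped ranking.
* **The divisor is out-degree, not out-strength.** A weighted variant
  (divide by out-strength, weight the numerator) is available behind
  `weighted = TRUE`.

Convergence is geometric with ratio $d$: the L1 change contracts like
$0.85^k$, which reaches about $4 \times 10^{-8}$ after the default cap of
100 iterations -- short of the default $10^{-9}$ tolerance. Hitting the
cap is deliberately a *flag* (in the returned summary, with a warning),
not an error: the bounded-iteration regime is part of the method's
definition. Callers who want the fixed point to full precision raise
`max_iter` to 200--500, which is what the package's own pipeline and test
oracles do; agreement with a direct linear solve of
$(I - d\,B^\top)\,x = (1-d)/n$ is then at the $10^{-13}$ level.

## Misinformation vulnerability centrality

MVC couples structural exposure with innate susceptibility. Each node
starts with a vulnerability $vul_0(v) \in [0, 1]$ and is amplified each
timestep by its degree:

$$vul_{t+1}(v) = \mathrm{degree}(v) \times vul_t(v)$$

The default degree mode is **in-degree** -- the number of sources that can
reach $v$ -- because vulnerability grows with exposure; out- or
total-degree model broadcast-type influence instead. After `steps`
iterations (default 5, the lower end of the typical five-to-ten regime)
the final scores are min--max normalised to $[0, 1]$.

**Initialisation hierarchy.** `initialise_vulnerability()` uses, in order
and with no silent mixing: an explicit `vul0` attribute covering every
node; otherwise observable susceptibility features (credibility,
unchecked-retweet counts, emotion-word counts), each min--max scaled,
averaged with equal weights, and rescaled; otherwise a seeded $U(0, 1)$
draw consumed in ascending node-id order so the same seed reproduces the
same vector on any platform.

**Numerics.** Because degree is fixed on a static snapshot, the recurrence
has the closed form $\mathrm{degree}(v)^{steps} \cdot vul_0(v)$. The raw
sequence grows geometrically for degree $> 1$ -- it does not stabilise --
so the implementation evaluates the closed form in log space and exploits
the fact that min--max normalisation is invariant to positive rescaling:
the normalised output is identical to normalising the literal recurrence,
without overflow. If every raw score is equal (e.g. an edgeless graph maps
everything to zero) the degenerate min--max maps all nodes to 0.5, the
midpoint, rather than asserting universal extreme vulnerability.

**What `steps` means.** Each extra step multiplies by degree once more, so
`steps` acts as an exposure weight: larger values tilt the ranking toward
connectivity and away from innate susceptibility, and two nodes whose
degree and vulnerability orderings disagree can swap ranks as `steps`
grows (degree 2 with $vul_0 = 1$ outranks degree 4 with $vul_0 = 0.2$ at
two steps, and trails it at three). What always holds -- and what the test
suite asserts -- is the dominance order: a node with at least the degree
and at least the vulnerability of another never ranks below it, at any
step count. The default of 5 keeps both ingredients visible.

## Dynamic influence centrality

Every node starts with influence 1; at each timestep it adds the current
influence of its in-neighbours:

$$DIC_{t+1}(v) = DIC_t(v) + \sum_{u \in N_{in}(v)} DIC_t(u),$$

equivalently $DIC_t = (I + A^\top)^t \mathbf{1}$ on the binary adjacency.
The trajectory is entrywise non-decreasing -- influence compounds, it never
decays -- so computation is bounded at a small step count (default 10) and
the final vector is normalised: division by the maximum by default
(rank-preserving and scale-invariant), min--max as an option. Growth is
geometric in the dominant adjacency eigenvalue; a guard aborts with advice
to reduce `steps` well before double overflow. Within the default regime
the recurrence is exact integer arithmetic in doubles, and the test suite
checks it entrywise against dense matrix powers.

**Persistence.** The point of DIC is *temporal* prominence: accounts that
stay near the top across snapshots rather than peaking once.
`persistence_profile()` counts, for each node, the timesteps it spends in
the top-k of the per-step max-normalised vector, breaking ties by final
score and then id. One rule needs stating: a step whose values are all
equal -- always true at $t = 0$, where every node is 1 -- carries no
ranking information, so it credits every node rather than handing the $k$
alphabetically-first ids a membership bonus.

## The comparison framework

`overlap_partition()` assigns every node in the union of several top-k
lists to exactly one block keyed by the exact subset of lists containing
it ("degree & eigenvector", "closeness-exclusive", ...); blocks are
disjoint and cover the union, so block counts always sum to the union
size. `coverage_gain()` is the percentage growth of the influencer union
when a metric family is extended, $100(|ext| - |base|)/|base|$, reported
to two decimals; it accepts explicit node sets or bare counts, and never
hard-codes any particular published figure -- it reports whatever its
inputs imply. `exclusivity_fraction()` reports what share of a candidate
top-k list is absent from every reference list.

`proxy_alignment()` validates a metric against an observable proxy (e.g.
retweet counts for influence, emotion-word counts for susceptibility):
top-k overlap plus a Spearman rank correlation computed literally as
$1 - 6\sum d_i^2 / (n(n^2 - 1))$ over full descending rankings with
midranks for ties. The literal formula is used, rather than Pearson on
midranks, because ranks are the representation the validation tables work
in; without ties the two coincide. The emotion-word proxy column is built
by whole-token, case-insensitive matching against a lexicon; a 30-term
synthetic fear/outrage/conspiracy word list ships as a clearly
non-canonical fixture.

## The intervention simulator

The cascade model is the **independent cascade**: each newly activated
node attempts once to activate each inactive out-neighbour with the edge's
transmission probability $p$ (or $\min(1, p \cdot w)$ in weighted mode),
until quiescence; spread is the activated count including seeds. Because
each edge fires at most once, the spread distribution is exactly that of
bond percolation: keep each edge independently with its probability and
count the nodes reachable from the seeds. The implementation simulates in
that representation, which buys three things: an exact deterministic
special case at $p = 1$ (pure reachability, pinned to an igraph oracle in
tests); *exact* common random numbers across intervention arms, because
the per-run edge-retention draws depend only on the configuration, never
on the removal set; and a trivially reproducible simulation given a seed.

`evaluate_intervention()` removes a node set (removed seed accounts are
neutralised -- deplatformed accounts cannot activate anyone), reruns the
same draws, and reports the percentage reduction in mean spread;
`strategy_comparison()` does this for several labelled removal sets under
the one set of draws. Defaults ($p = 0.1$, 1000 runs, seed 7) are logged
in every outcome's provenance. Published headline reductions from any
particular dataset are outcomes of an unspecified simulation on that
dataset; this simulator makes no attempt to reproduce such figures, only
the defined model above.

## The synthetic generator

`generate_network()` emulates a retweet-style interaction graph with
planted, manifest-recorded ground truth:

* **Growth**: directed preferential attachment -- each arriving node sends
  `attachment_out` (default 3) edges to existing nodes chosen proportional
  to in-degree + 1, over a small seed cycle. This yields the heavy-tailed
  in-degree profile of real retweet graphs (at the default $n = 500$ the
  maximum in-degree is several times the median).
* **Planted hubs**: extra in-edges from distinct sources, drawn with the
  same popularity-proportional rule (mega-hubs are retweeted by
  influential accounts too), until the hub clears the grown graph's
  natural maximum in-degree by the `hub_boost` margin (default 20). Hubs
  therefore occupy the top in-degree ranks by construction.
* **Planted vulnerable amplifiers**: the same in-edge boost *plus* an
  initial vulnerability drawn from `[0.9, 1]`, while everyone else draws
  from `U(0, 0.85)` -- the "well connected and credulous" profile, with
  the planted nodes at the top of the vulnerability ranking by
  construction.
* **Planted persistent spreaders**: each fed by an insular echo chamber of
  nine partners in a fully reciprocal clique. Chamber members are rewired
  to interact only inside the chamber; the clique's cumulative influence
  compounds geometrically ($\sim 9^t$), overtakes the attachment core
  within a few steps, and accrues to the planted node, which stays
  strictly above its partners because they do not hear back from it.
* **Attributes**: `retweet_count` rank-correlated with in-degree and
  `emotion_word_count` with `vul0` via bounded multiplicative noise
  (transparent and testable, rather than a parametric copula);
  `misinfo_seed` flags drawn at the configured fraction; optional
  disconnected reciprocal-pair "islands" for exercising the harmonic
  closeness fallback.

Everything is reproducible bit-for-bit from `(spec, seed)`; random draws
consume nodes in ascending-id order.

**Recovery fixtures are single-structure by design.** The hub-recovery
check (does PC's top-5 find the planted hubs?) runs on networks planting
only hubs; the vulnerability-recovery check (does MVC's top-5 find the
planted amplifiers?) on networks planting only amplifiers. The reason is
arithmetic, not convenience: MVC's raw score is
$\mathrm{degree}^{steps} \cdot vul_0$, so at five steps a bounded
$vul_0 \in [0, 1]$ can never compensate a material degree deficit --
whichever planted family holds the top in-degree ranks wins *both*
rankings. Planting both structures in one graph therefore makes the two
recoveries compete by construction; the generator supports simultaneous
planting for pipeline exercises, but recovery is only a meaningful claim
per structure.

**What the generator does not emulate**: real post text (the emotion
counts are synthetic), temporal edge dynamics (all metrics run on a static
snapshot; DIC's timesteps are model iterations, not data timestamps),
community structure beyond the planted motifs, and real-world scale.
Passing the planted-recovery tests shows the metrics recover the
structures they are designed to detect under controlled conditions -- not
that they identify real misinformation influencers, which requires
labelled data no synthetic benchmark can substitute for.

## Problem sizes and numerical checks

The verification suite pins each computation to an independent oracle at
sizes chosen to make the oracles exact and exhaustive: PC against a dense
linear solve on random digraphs up to $n = 50$; betweenness against
exhaustive simple-path enumeration up to $n = 8$; MVC against the literal
recurrence with dyadic initial vulnerabilities ($k/256$), which make both
routes exactly representable in doubles so equality is exact; DIC against
dense matrix powers up to $n = 30$, ten steps, in exact integer range;
planted-structure recovery on twenty $n = 500$ networks; cascade
calibration on the single-edge analytic expectation ($1 + p$ at 10,000
runs) and the $p = 1$ reachability identity; and intervention dominance
(PC top-10 removal vs random removal) across twenty seeded networks.
`scripts/acceptance.R` recomputes all of these from scratch, plus the
published-arithmetic quantities, from a single command-line seed.

## Known limitations

* MVC's multiplicative recurrence makes degree dominate after a few steps;
  with random $U(0,1)$ initialisation its ranking is close to an in-degree
  ranking with noise. The feature-based initialisation is the mode in
  which MVC adds information.
* DIC has no decay or saturation; its trajectory is monotone by
  construction, so "waning" influence cannot be represented -- only
  persistent accumulation. Decay variants are a natural extension and are
  deliberately out of scope.
* The cascade simulator covers the independent-cascade family only; no
  threshold models, no temporally ordered edge activations.
* Closeness and betweenness are exact, not approximated; graphs far beyond
  $10^4$ nodes will want sampling approximations this package does not
  provide.
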