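---
title: "Density-degree seeded k-means community detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-degree seeded k-means community detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddjkm)
```

## The problem

Given an undirected, unweighted simple graph and a known number of
communities $K$, partition the nodes into $K$ dense, weakly inter-connected
blocks. k-means is attractive for this because it is fast and scales to
large graphs, but it has a well-known fragility: randomly chosen initial
centers can land in the same community, or on isolated nodes, and the final
partition inherits those mistakes. This package implements a deterministic
seeding strategy built from two node-level quantities, plus the k-means
stage itself, the evaluation metrics, and the synthetic benchmarks used to
exercise the whole pipeline.

## Node-level measures

**Ball density.** For node $v$, let $S$ be the $h$-hop BFS ball (the node
itself plus everything within shortest-path distance $h$) and $G' = (V',
E')$ the subgraph it induces. The density of $v$ is

$$\mathrm{Density}(v) = \frac{|E'|}{|V'|(|V'|-1)/2} \in [0, 1],$$

the induced edge count over its maximum. Nodes buried inside one community
have dense balls; nodes whose ball straddles a community boundary pick up
many non-edges and score low. Density is a computable stand-in for the
community-belongingness uncertainty — the base-2 Shannon entropy of the
ball's distribution across communities (`cb_uncertainty()`) — which cannot
be used for seeding because it requires the very partition we are after.
A ball with a single node (an isolated vertex) is given density 0 by
convention, which also forces its DD score (below) to 0.

**DD score.** Degree centrality alone concentrates seeds in the largest
community; density alone favours tiny cliques on the periphery. The seeding
criterion is their product, $\mathrm{DD}(v) = \mathrm{Density}(v) \times
\deg(v)$. Note $\mathrm{DD}(v) = 0$ exactly when $v$ is isolated: any node
with an edge has a ball of at least two nodes and one edge, hence positive
density.

**Jaccard similarity.** Node affinity is measured by the Jaccard
coefficient of open neighborhoods, $|N(u) \cap N(v)| / |N(u) \cup N(v)|$.
The $n \times n$ matrix $J$ of all pairwise coefficients (unit diagonal by
convention; stored sparse since most pairs share no neighbor) plays two
roles: its rows are the k-means feature vectors, and, scaled by density, it
measures seed redundancy. The diagonal convention only shifts every feature
vector by the same amount and cannot change any distance comparison between
rows.

**DDJ matrix.** $\mathrm{DDJ} = (D D^\top) \circ J$ where $D$ is the
density vector and $\circ$ the Hadamard product: a density-weighted
similarity used to keep seeds apart.

## Seed selection

1. The first seed is the node with maximal DD.
2. Each subsequent round computes, for every remaining candidate $p$, the
   mean DDJ entry between $p$ and the current seeds ($R_p$); the candidates
   attaining the minimum $R_p$ are collected and the one with the largest DD
   joins the seed set.
3. Repeat until $K$ seeds are chosen.

Ties are broken by ascending node id at both the DD ranking and the final
choice, making the procedure fully deterministic. A candidate in a different
component from all seeds has $R_p = 0$, the minimum, which is precisely what
drives seeds into different components and communities.

One design point was genuinely open. With candidates unrestricted, an
isolated node (DD $= 0$, $R_p = 0$) would be *forced* into the seed set
whenever every connected candidate retains positive correlation to some
seed — for example two 5-cliques plus one isolated node at $K = 3$. Since a
central goal of DD seeding is that isolated nodes are never chosen as
centers, the candidate pool is restricted to nodes with DD $> 0$ while any
remain; the DD $= 0$ pool is used only once the positive-DD nodes are
exhausted (so $K = |V|$ still works). On graphs without isolated nodes this
changes nothing.

## The k-means stage

Feature vectors are the raw rows of $J$ (no normalization); distances are
Euclidean. Initial centroids are the rows of the seed nodes. Each iteration
assigns every node to its nearest centroid (ties to the lowest cluster
index) and recomputes centroids as member-row means. Iteration stops when
the assignment is unchanged between consecutive iterations, when the
maximum centroid displacement falls below `tol` ($10^{-9}$ by default), or
at `max_iter` (100 by default; observed iteration counts on the benchmarks
below are typically under 20). The stopping rule interprets "the centers
stop moving" as either exact assignment stability or numerically negligible
displacement, whichever comes first.

If a cluster empties mid-iteration it is reseeded with the row of the node
currently farthest from its assigned centroid (largest first, ties by id).
This is deterministic and guarantees the output has exactly $K$ non-empty
blocks, which the output contract requires. The random-initialization
baseline (`random_init_kmeans()`) differs from the seeded method *only* in
drawing $K$ distinct initial nodes uniformly at random.

## Evaluation metrics

**NMI** is computed from the confusion matrix $C$ of the two partitions as
$2 I(A;B) / (H(A) + H(B))$; the log base cancels. $0 \log 0 = 0$. If both
partitions are a single block the normalizer vanishes; the value is defined
as 1 with a warning (the partitions are then identical). `nmi()` is checked
in the test suite against a brute-force evaluation of its defining sum and
against igraph's independent implementation to $10^{-9}$.

**Bidirectional best-match F1** averages, in both directions, the best
per-community harmonic mean of precision and recall; zero-overlap pairs
contribute 0. It is computed on community node-sets, so it accepts both
disjoint partitions and overlapping ground-truth collections.

## Synthetic benchmarks

`generate_lfr()` emulates the LFR benchmark family: degrees follow a
truncated power law with exponent $\tau_1$ (the lower cutoff solved by
integer scan so the expected mean matches $\langle k \rangle$; the draw is
retried unless the realized mean is within 10% of target), community sizes
follow a truncated power law with exponent $\tau_2$ on $[C_{\min},
C_{\max}]$ tiled to sum exactly to $N$ (the residue is spread over
communities with slack, bounded retries), and each node places a fraction
$1 - \mu$ of its edges inside its community. Truncation makes the
$\tau_2 = 1$ size law proper despite being improper on an unbounded domain.

Nodes are assigned to communities in decreasing internal-degree order,
uniformly among communities with a free slot and enough members to host the
node's internal degree; when none fits, the node goes to the largest
available community and its internal degree is capped at (size − 1), the
excess moving to its external degree. Internal degree sequences are
realized exactly per community via Viger–Latapy sampling where feasible
(falling back to a heuristic simple-graph sampler, then to stub matching
with bounded rewiring); external stubs are matched under the constraints
simple + inter-community. The handful of stubs that cannot be placed are
dropped, so the realized mean degree can sit slightly below target; the
instance reports its realized mean degree and realized mixing so nothing is
hidden. Because internal/external degrees are integer roundings of
$\mu \cdot k$, the node-averaged realized mixing sits slightly above the
nominal $\mu$ at small $\mu$ (e.g. ≈ 0.12 at $\mu = 0.1$ for
$\langle k \rangle = 15$) — a granularity effect shared with the original
LFR construction, bounded in the tests at ±0.05.

What the generator does *not* emulate: degree–community correlations,
clustering beyond what the degree sequence implies, weighted or
overlapping communities, and bit-level equivalence with the reference LFR
program. Benchmark comparisons against published LFR results are therefore
statistical, not exact, and the acceptance checks use tolerances sized
accordingly (±0.05 on mean NMI for $\mu \le 0.3$, ±0.10 at $\mu = 0.4,
0.5$).

`generate_planted_partition()` (equal-block SBM via igraph) and
`ring_of_cliques()` provide small controllable fixtures: the former for
statistical unit tests with binomial closed forms, the latter as a
deterministic structure where bridge endpoints demonstrably have lower ball
density than community interiors.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `h` | 3 | BFS-ball radius for density; 3 reflects the small-world regime where larger balls blur into the whole graph. Toy examples in the documentation use `h = 2` where stated. |
| `K` | required | number of communities; estimating it is out of scope by design. |
| `max_iter` | 100 | k-means cap; convergence is typically far earlier. |
| `tol` | 1e-9 | centroid-displacement threshold, in Jaccard-row distance units. |

## Problem sizes used in the packaged experiments

The packaged replication runs 5 replicate 5000-node instances per mixing
value at $\mu = 0.1, \dots, 0.5$ (sizes 20–100, $\langle k \rangle = 15$,
$k_{\max} = 75$), and a 1000-node sweep ($\mu = 0.1, \dots, 0.9$, 10
replicates, seeded vs random initialization) for the ordering and
degradation checks. These are the package's own desk-scale choices;
`run_benchmark()` exposes the replicate count so larger replications are
one argument away. Mean and standard deviation are both reported.

## Known limitations

- Dense Jaccard rows: on graphs with heavy degree overlap the similarity
  matrix loses sparsity and memory grows toward $O(n^2)$.
- The method requires $K$; a wrong $K$ forces merges or splits (the
  empty-cluster repair guarantees $K$ blocks even when the data disagree).
- Seeding quality degrades as mixing grows: past $\mu \approx 0.6$ on the
  1000-node family, accuracy drops sharply for both seeded and random
  initialization — community structure is simply no longer there to find.
- Disconnected graphs are accepted (isolated nodes are retained, never
  seeded, and absorbed into whichever cluster their zero feature vector is
  nearest to), but the method is designed for largely connected networks.
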