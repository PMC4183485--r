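---
title: "Module detection and node-role cartography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module detection and node-role cartography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcarto)
```

This vignette documents the models implemented by **modcarto**, the
parameters that matter, and the numerical and design choices made where
more than one reasonable convention exists.

## Data model and its assumptions

Networks are undirected simple graphs over opaque, case-sensitive string
labels. Node order is insertion order, which makes every matrix view
(adjacency, Laplacian, distance) reproducible. Three normalisations are
applied on construction and are deliberate modelling choices:

* duplicate edges and the two orientations of a pair collapse silently
  to one undirected edge — edge-list files in the wild routinely list
  both directions;
* self-loops are dropped with a warning — none of the module statistics
  below is defined for them;
* edge weights (the optional third `.abc` column) are parsed, stored and
  written back, but **ignored by every computation**. All clustering
  engines and the cartography operate on the binary adjacency matrix;
  the weighted view exists for export only. Users with meaningful
  weights should threshold them into topology before import.

A partition is a total map from nodes to module labels; every operation
that consumes one validates totality first and fails on missing or
foreign nodes rather than guessing.

## Clustering engines

### Spectral

`spectral_partition()` embeds node $i$ as row $i$ of the matrix $U$
whose columns are the eigenvectors of the $k$ smallest eigenvalues of a
graph Laplacian, then runs Euclidean k-means on the rows. Two Laplacians
are available: unnormalized $L = D - A$ and the random-walk normalized
form $L = I - D^{-1}A$ (default), with the row of a degree-zero node
replaced by its identity row so the matrix stays well defined on graphs
with isolates. The random-walk form was chosen over the symmetric
variant because it is the one underlying the Meila–Shi random-walk view
of spectral clustering; for a disconnected graph its zero-eigenvalue
eigenvectors are exactly the component indicators, which is why the
engine needs no connectivity assumption.

Two numerical conventions make the embedding deterministic: eigenvalues
are sorted ascending with R's stable order, and each eigenvector's sign
is fixed by making its first entry larger than $10^{-8}$ in magnitude
positive. Without the sign fix, repeated runs could hand k-means
reflected point clouds and produce different (if equivalent) restarts.
The normalized Laplacian is not symmetric, so its eigendecomposition is
computed by the general routine and the (provably real) eigenvalues are
taken as their real parts.

### k-means on graph metrics

k-means needs a vector space — the SSE objective
$\sum_c \sum_{x \in c} \lVert x - \mu_c \rVert^2$ and the
centroid-as-mean identity do not transfer to raw dissimilarities. Nodes
are therefore embedded as rows of a full distance matrix and clustered
in that $n$-dimensional Euclidean space (a medoid variant is a
non-goal). Two graph metrics are offered:

* **shortest path**: unweighted BFS hop counts. Unreachable pairs get
  the finite surrogate $n$, strictly larger than any true path length;
  this keeps disconnected graphs embeddable while pushing components
  far apart, which is the behaviour one wants from a clustering metric.
* **Hamming**: the number of coordinates at which two adjacency rows
  differ, over all $n$ coordinates (so two adjacent nodes always differ
  in at least the two coordinates naming each other).

The Lloyd solver uses k-means++ initialisation, centroids as arithmetic
means, ties in assignment broken toward the lowest cluster index, and
the best of `restarts` runs (default 10) by SSE. An empty cluster
arising mid-iteration is reseeded with the point farthest from its
current centroid — the standard repair that preserves the monotone
descent of the SSE. On small instances (up to 8 points, up to 3
clusters) the solver with 50 restarts matches an exhaustive-enumeration
oracle over all $k^n$ assignments in the test suite; restarts trade run
time for optimality on larger inputs.

`sse_scan()` reports SSE as a function of $k$ for the elbow heuristic.
Automatic elbow detection is deliberately not implemented: the elbow is
a visual diagnostic, and any numeric rule (largest second difference,
distance to chord, ...) encodes an arbitrary preference the user should
make explicitly. Per-$k$ seeds are derived as `seed + k` so the scan is
reproducible yet each $k$ gets an independent restart sequence.

### MCL

`mcl_partition()` implements the Markov Cluster iteration: add unit
self-loops (the standard stabilisation that damps the period-2
oscillation of bipartite-ish flows), column-normalize to a stochastic
matrix, then alternate expansion (matrix squaring) with inflation
(elementwise power $r$, entries below `prune_threshold` zeroed, columns
renormalized). Iteration stops when the matrix changes by less than
`tol` in max-norm (default $10^{-6}$) or after `max_iter = 200` rounds;
non-convergence returns the current partition with a warning and a
`converged = FALSE` attribute rather than failing, since near-idempotent
states are already informative. Clusters are the connected components of
the nonzero structure of the converged matrix, which is total by
construction; with the default inflation 2 the flow on two cliques
sharing one bridge edge collapses onto two attractors, the canonical
sanity check. Inflation is the granularity dial: values above 2 fragment
more, values toward 1 merge (exactly 1 is rejected — the iteration
would be pure diffusion and converge to one block regardless of
structure).

## Cartography

With a partition fixed, let $k_i$ be node $i$'s degree and
$\kappa_{is}$ its links into module $s$, $\kappa_i$ those into its own
module.

**Within-module z-score.** $z_i = (\kappa_i - \mu) / \sigma$ with
population (divide-by-$n$) moments, matching the original cartography's
standardisation; a sample SD would inflate $z$ in small modules. The
default takes $\mu, \sigma$ over the node's own module. A `global` mode
standardising over all nodes is provided as a sensitivity check because
the two readings genuinely disagree in the literature this formula
descends from; within-module is the default since it is what makes $z$
a *within-module* hub score. Degenerate case: $\sigma = 0$ (regular
module) yields $z = 0$ for all members.

**Participation.** The original
$P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$ is capped at $1 - 1/N$: with
four modules no node can exceed 0.75, so the nodes whose links are
*mostly elsewhere* — the functionally interesting connectors — are
compressed against the ceiling. The modified default
$P_i = 1 - (\kappa_i/k_i)^2$ keeps only the own-module term: it is
independent of $N$, attains 1, and always dominates the original
($\sum_s f_s^2 \ge f_{own}^2$), which the test suite checks as an
invariant. Isolated nodes take $P = 0$ by convention (no links, no
participation), and $z = 0$ via the $\sigma = 0$ rule, landing them in
R1.

**Regions.** Hubs are $z \ge 2.5$. Non-hub cuts default to
$0.05 / 0.62 / 1 - 0.35^2$; hub cuts to $0.30 / 0.75$; upper boundaries
belong to the lower region and $z = 2.5$ is a hub. The R3/R4 boundary
is *defined* as $1 - 0.35^2$ (and computed as that expression, so the
boundary case $\kappa/k = 0.35$ lands in R3 without floating-point
surprises): under the modified $P$, region R4 is then literally "fewer
than 35 % of the node's links inside its own module". The remaining
cuts follow the classical cartography. All seven are parameters of
`region_thresholds()` because the region semantics — not the specific
numbers — are the invariant part of the method.

## Network builders

* `contact_network()`: edge iff the Cα–Cα Euclidean distance lies in
  the **closed** interval $[d_{min}, d_{max}]$, default 4–8 Å.
  "Within 4 and 8" is ambiguous at the endpoints; closed was chosen and
  both ends are configurable. The 4 Å floor already excludes covalently
  bonded sequence neighbours (≈ 3.8 Å), so no sequence-separation
  filter is applied.
* `coexpression_network()`: edge iff $|r| >$ threshold (strict, default
  0.8), Pearson over pairwise-complete samples. Pairs with fewer than 3
  complete samples are skipped with a warning (two points always
  correlate perfectly); zero-variance genes have undefined $r$ and
  produce no edges.
* `erdos_renyi_gm()` is the $G(n, m)$ model — exactly $m$ edges — not
  $G(n, p)$, because reference figures in this line of work fix both
  counts (e.g. 1000 nodes, 50 000 edges).
* `barabasi_albert()` seeds with a clique on $m+1$ nodes and attaches
  each new node to $m$ distinct existing nodes with probability
  proportional to current degree (sequential weighted sampling without
  replacement). The clique seed gives every initial node nonzero
  degree, so no zero-appeal correction is needed and the edge count has
  the closed form $\binom{m+1}{2} + (n - m - 1)m$.
* `planted_partition()` draws every within-module pair with $p_{in}$
  and every between-module pair with $p_{out}$, independent Bernoulli,
  and returns the ground truth partition.

## What the synthetic generators do and do not emulate

The planted-partition model is the package's module-recovery fixture:
equal-size blocks, homogeneous degrees within blocks, independent
edges. The default recovery experiment uses 4 modules of 25 nodes with
$p_{in} = 0.5$, $p_{out} = 0.02$ — assortative, above the detectability
regime, the setting in which a correct spectral implementation should
recover the planted labels essentially perfectly, so failures indicate
bugs rather than statistical bad luck. Real biological networks violate
all three homogeneity assumptions (broad degree distributions, nested
and overlapping modules, correlated edges), so passing recovery tests
demonstrates algorithmic correctness, not expected accuracy on real
data. Likewise the Barabási generator reproduces a heavy degree tail
but none of the local clustering or motif structure of real
interactomes.

Test and acceptance problem sizes were chosen to exercise each code
path at desk scale: 100-node planted graphs for spectral recovery (10
seeds), 1000-node graphs for generator contracts, ≥ 200 random
instances of ≤ 8 points for the exhaustive k-means oracle, 100 random
partitioned graphs for the cartography invariants, 50 random instances
for I/O round-trips.

## File formats

`.abc`: two or three whitespace-separated fields per line (source,
target, optional numeric weight); runs of spaces or tabs both split;
`#` lines and blank lines are skipped. Malformed lines fail with their
line number. `.idx`: node label, cluster label; same lexical rules;
conflicting reassignment of a node is an error. Isolated nodes cannot
be expressed in `.abc`, so writing a network that has them warns rather
than silently losing them. Expression tables are TSV with gene rows and
sample columns; `NA`/empty cells stay missing and are never imputed as
zero. PDB input takes the first CA record per residue (first altLoc
encountered wins, HETATM excluded) and labels residues
`chain:resSeq[insertionCode]`. Result tables print floats with 6
significant digits so that regression diffs are stable across
platforms.

## Command-line interface

`inst/exec/modcarto` exposes the pipeline as subcommands
(`build-contact`, `build-coexpr`, `simulate`, `cluster`, `sse-scan`,
`cartography`, `run-all`). Seeds default to 0 and are embedded as a
`# seed=<n>` header in every output file, making runs self-describing;
identical argument vectors yield byte-identical outputs. Exit codes
separate usage errors (2) from missing inputs and runtime failures (1).

## Known limitations

* Weighted, directed and multigraph analyses are out of scope; weights
  are carried through I/O only.
* The cartography assumes a hard partition; overlapping or hierarchical
  community structures are not represented.
* The spectral engine computes a dense eigendecomposition ($O(n^3)$)
  and the graph k-means embeds nodes in $n$ dimensions; both are meant
  for networks up to a few thousand nodes, not genome-scale graphs.
* MCL cluster extraction via connected components merges the rare
  overlapping attractor systems instead of splitting ties by flow
  magnitude; at convergence with default pruning the distinction has
  not been observed to matter.
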