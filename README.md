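# modcarto

Modular clustering of undirected networks and a node-role **cartography**:
every node is placed in the plane spanned by its participation coefficient
*P* and its within-module z-score *z*, and assigned one of seven
topological roles. The approach is aimed at systems-biology networks —
protein contact maps, gene co-expression graphs, interactomes — where the
mesoscopic (module) level links topology to function: residues that
bridge protein sub-units, or genes that co-express across developmental
modules, surface as high-*P* "kinless" nodes.

## The method

Given a partition of the network into modules:

* **within-module z-score** — with κ<sub>i</sub> the number of links of
  node *i* inside its own module,
  *z<sub>i</sub>* = (κ<sub>i</sub> − ⟨κ⟩) / σ<sub>κ</sub>, mean and
  population SD taken over the nodes of *i*'s module (a `global` mode
  standardizing over all nodes is also provided). Nodes with
  *z* ≥ 2.5 are module hubs.
* **participation coefficient** — the classical definition
  *P<sub>i</sub>* = 1 − Σ<sub>s</sub> (κ<sub>is</sub>/k<sub>i</sub>)²
  sums over all modules *s* and is bounded by 1 − 1/N for N modules
  (0.75 for 4 modules), which masks strongly inter-modular nodes when N
  is small. The package's default is therefore the **modified**
  single-term variant
  *P<sub>i</sub>* = 1 − (κ<sub>i</sub>/k<sub>i</sub>)², which is
  independent of the module count and reaches 1.
* **role regions** — non-hubs split on *P* into R1 (ultra-peripheral),
  R2 (peripheral), R3 (non-hub connector) and R4 (non-hub kinless);
  hubs into R5 (provincial), R6 (connector) and R7 (kinless). The
  default R3/R4 boundary is 1 − 0.35² = 0.8775, so R4 collects exactly
  the nodes with fewer than 35 % of their links inside their own module.
  All seven cuts are configurable via `region_thresholds()`.

The cartography is clustering-agnostic: partitions can be loaded from
`.idx` files or produced by the built-in engines —

* **spectral** (Meila–Shi style): k-means on the rows of the
  eigenvectors of the *k* smallest Laplacian eigenvalues (random-walk
  normalized `I − D⁻¹A` by default, or unnormalized `D − A`);
* **k-means** on graph metrics: nodes embedded as rows of the
  shortest-path or Hamming distance matrix, Lloyd iterations with
  k-means++ seeding and restarts, plus an SSE-vs-k scan
  (`sse_scan()`) for the elbow heuristic;
* **MCL**: alternating expansion (matrix squaring) and inflation
  (elementwise power + column renormalization) of the column-stochastic
  flow matrix until convergence.

Builders construct networks from data: `contact_network()` links
residues whose Cα–Cα distance falls in a closed 4–8 Å window (from
`read_pdb_ca()` coordinates), `coexpression_network()` links genes with
|Pearson r| > 0.8 across samples, and `erdos_renyi_gm()`,
`barabasi_albert()` and `planted_partition()` provide reference random
graphs.

## Worked example

```r
library(modcarto)
pp  <- planted_partition(3, 8, p_in = 0.9, p_out = 0.05, seed = 1)
net <- pp$network
net
#> <network: 24 nodes, 90 edges>
p <- spectral_partition(net, 3, seed = 1)
p
#> <partition: 24 nodes in 3 modules (sizes 8, 8, 8)>
rec <- build_cartography(net, p)
head(rec, 5)
#>   node module degree kappa       z      P region
#> 1   n1     M1      7     7  0.7071 0.0000     R1
#> 2   n2     M1      7     6 -0.7071 0.2653     R2
#> 3   n3     M1      6     5 -2.1213 0.3056     R2
#> 4   n4     M1      8     7  0.7071 0.2344     R2
#> 5   n5     M1      7     6 -0.7071 0.2653     R2
table(rec$region)
#> R1 R2
#>  6 18
```

Spectral clustering recovers the three planted modules exactly. Node
`n1` keeps all 7 links inside its module (κ = k, so P = 0: region R1,
ultra-peripheral); `n3` sends two of six links to other modules
(P = 1 − (5/6)² ≈ 0.31: region R2, peripheral). No node reaches the
hub band (z ≥ 2.5) in a graph this small and regular.
`write_node_table(rec, "table.tsv")` exports the table and
`pz_scatter(rec, "pz.png")` draws the P–z portrait with the region
boundaries.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/exec/modcarto simulate --model planted --modules 3 --size 8 \
    --p-in 0.9 --p-out 0.05 --seed 1 --out net.abc
Rscript inst/exec/modcarto run-all --input net.abc --algorithm spectral \
    -k 3 --seed 1 --outdir results/
```

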