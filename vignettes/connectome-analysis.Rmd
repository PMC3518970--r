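---
title: "Analysing meso-scale connectomes with mesoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing meso-scale connectomes with mesoconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoconn)
```

## The data model and its assumptions

A meso-scale connectome is not observed as a graph; it is assembled from
literature-curated *connection records*, one per documented tract-tracing
result: source region, target region, laterality (ipsi- or contralateral),
and an ordinal weight code 0–9, where 0 means the projection was
investigated and reported absent and 9 is the strongest label. Regions
live in a rooted "is part" ontology, and the analysable graph depends on
the chosen *view*: collapsing a branch turns its root into a leaf and
makes records attached anywhere in the branch aggregate up to it. The
visible leaves, in depth-first document order, fix the node order of
every matrix — never alphabetical order, because the curated hierarchy
is the scientifically meaningful arrangement.

Three modelling commitments are made at construction time:

* **Cross-study weight fusion is the maximum code.** The literature gives
  no calculus for combining semiquantitative labels from independent
  experiments; the maximum preserves "the connection exists at least this
  strongly", and the supporting record count is kept separately in
  `n_studies` so no information is lost. Records whose aggregated maximum
  is 0 produce no arc.
* **Graphs are simple and loop-free.** Self-projections are excluded;
  motif, distance and vulnerability analysis all assume a simple digraph.
* **Weights are labels, not capacities.** Every topological quantity
  (distances, clustering, communicability, motifs, closeness) uses the
  binarized graph. The ordinal codes travel through the pipeline as arc
  annotations (e.g. in pathway output) but never enter a shortest-path or
  matrix-exponential computation.

Condensation (`condense()`) iteratively removes regions lacking either
any input or any output, to a fixpoint. Regions without documented
afferents or efferents cannot carry flow; keeping them would bias every
comparison against randomized networks. All headline analyses operate on
the condensed network.

## Global parameters

`global_summary()` reports average valency $2E/N$, line density
$100\,E/(N(N-1))$ %, heterogeneity (population SD of valency over its
mean), average path length $L$, average cluster coefficient $C$,
centrality, a power-law fit error, and modularity $Q$. Choices where the
field's conventions genuinely diverge:

* **Unreachable pairs are excluded from $L$**, and the reachable fraction
  is reported alongside; a single-node graph reports `NA`, never 0. The
  alternative (restriction to the largest strong component) can be had by
  condensing to that component first.
* **Clustering is computed on the underlying undirected graph**; the
  directed in/out variants are exposed per node in the local table
  (`CCo`, `CCi`) but the global average uses the classic coefficient.
* **Centrality** defaults to mean degree centrality
  $\mathrm{valency}/(2(N-1))$; mean harmonic closeness is available via
  `centrality = "closeness"` because the verbal definition ("links
  incident upon a node") is ambiguous between the two in parts of the
  literature.
* **Small-worldness** $S = (C/\bar C_{ER}) / (L/\bar L_{ER})$ uses a
  seeded Erdős–Rényi ensemble matched in $N$ and $E$; it is `NA` when the
  ensemble clustering averages zero.
* **Power-law error** fits $P(k) \propto k^{-\gamma}$ by least squares on
  the log–log valency histogram (zero bins excluded) and reports 100
  times the mean absolute deviation; it needs at least three distinct
  valencies, else `NA`.

Modularity uses the *directed* Newman quality
$Q = \sum_{ij} (A_{ij}/E - k^{out}_i k^{in}_j / E^2)\,
\delta(c_i, c_j)$, maximized by greedy agglomeration plus single-node
reassignment sweeps. The heuristic is deterministic under its seed; on
graphs with up to 6 nodes it matches exhaustive partition search in ≥
29/30 random instances in the test suite (the one permissible miss is a
documented tolerance of greedy agglomeration, not a defect of the $Q$
evaluation, which the tests check exactly on closed-form cases: two
disjoint 3-cycles give $Q = 1/2$, a complete digraph $Q = 0$).

## The local parameter table

`local_table()` mirrors the classic 30-column per-region table. Most
columns are standard (degrees, eccentricities, harmonic closeness
normalized by $n-1$, unnormalized directed betweenness and stress,
Katz status with attenuation $\alpha = 0.9/\lambda_{max}$ and unit
exogenous input — the attenuation is configurable because published
tables rarely state it). Interpretive choices, each isolated in one
replaceable function:

* **Eigenvector centrality** is computed on in-direction influence and
  normalized so the top region scores exactly 1, matching the common
  presentation of such tables.
* **Radiality** is the reversed-distance mean
  $\sum_j (\mathrm{diam} + 1 - d(i,j)) / (n-1)$ over reachable targets;
  **centroid value** is the pairwise closeness-dominance minimum
  $\min_{w} (\gamma_v(w) - \gamma_w(v))$; both follow the standard
  centrality-suite definitions, and both come in out- and in-distance
  orientations because the orientation convention of printed tables is
  not fixed.
* **A "LC" column** seen in some published tables has no recoverable
  definition and is deliberately not implemented.

### Shapley rates

The Shapley rate treats regions as players in a cooperative game whose
characteristic function is the number of strongly connected components of
a coalition's induced subgraph. A region's value is its average marginal
contribution over arrival orders; values sum to the SCC count of the full
network. A region whose arrival merges many components gets a low
(negative) value — these are the structurally important regions. Exact
evaluation enumerates subsets (feasible to 10 nodes; the implementation
uses the subset-weighted closed form rather than the $n!$ orderings);
Monte-Carlo evaluation averages over random orderings and, for up to 12
nodes, uses a precomputed bitmask value table so that $10^5$ permutations
run in seconds. On the 8-node validation fixture the Monte-Carlo values
match exact enumeration within 0.02 at $10^5$ permutations.

## Motif census and significance

All isomorphism classes of weakly connected loop-free digraphs are
enumerated by scanning every arc configuration ($2^6$ for triads,
$2^{12}$ for tetrads) and grouping by a canonical code: the minimum, over
node permutations, of the row-major off-diagonal bitstring. Classes are
numbered `k-NN` by ascending arc count, ties broken by ascending
canonical code. This ordering reproduces the conventional anchors — the
two-arc divergence/chain/convergence classes are `3-01`–`3-03`, the
directed cycle is `3-07`, the one-mutual-plus-arc class is `3-04`, the
two-mutual class `3-09`, and the fully reciprocal triad `3-13` — and is
pinned by regression test. Counting is *induced*: each weakly connected
$k$-subset contributes to exactly one class, so class totals partition
the connected subsets. The subset scan itself is delegated to igraph's
compiled census and mapped onto the package's class order; the test suite
verifies it against an independent classify-every-subset oracle.

Significance uses the degree-preserving rewiring null: repeated double
arc swaps ($a{\to}b, c{\to}d \Rightarrow a{\to}d, c{\to}b$), rejecting
swaps that would create self-loops or duplicates, until
`swap_multiplier` × $E$ *successful* swaps have been performed (a
saturated graph, where no legal swap exists, is returned unchanged). The
reported $p$ is the fraction of replicates whose count is at least the
real count, so $p = 0$ means "more frequent than in every replicate" and
$p = 1$ "at most as frequent as every replicate"; $z$ is
$(f_{real}-\bar x)/\sigma$ with the convention $z = 0$ when $\sigma = 0$.

## Vulnerability

Closeness is harmonic — the mean of inverse distances, with unreachable
targets contributing 0 — because deletion analysis routinely disconnects
the graph and the raw inverse-sum is then undefined; on strongly
connected graphs the harmonic form is a monotone reparameterization of
the classic one. Node significance compares the mean closeness before
deletion with the mean over the *surviving* regions after deletion (the
deleted region has no closeness to average), expressed in percent of the
baseline; arc significance keeps the node set fixed. Negative node values
are legitimate (removing a poorly connected region can raise the
surviving mean); arc values cannot be negative beyond floating-point
noise, since deleting an arc can only lengthen distances. Every value is
reproduced to $10^{-12}$ by a brute-force recompute-from-scratch oracle
in the test suite.

## Connectivity profiles (PCA)

The 6 features per region are degree all, average neighbour degree,
clustering, 2nd-neighbour clustering, the variation coefficient of
neighbour degrees, and locality. The latter two definitions live in
scattered methodological literature; the readings implemented (each one
small replaceable function) are: `CluC_2` is the mean undirected
clustering over the 2nd-neighbour ring, and `Loc` is the fraction of arcs
touching the closed 1st neighbourhood that stay inside it. Features are
z-score standardized before PCA — they mix raw degrees with unit-interval
coefficients, so raw-scale PCA would be dominated by degree; a flag
disables standardization. Component signs are fixed by making each
component's largest-magnitude loading positive. The Parzen surface is an
isotropic Gaussian kernel average on a grid padded four bandwidths beyond
the data hull (bandwidth: Silverman's rule averaged over the two axes,
since published analyses rarely print theirs); its grid integral is 1
within 2%.

## Pathway search

`staged_paths()` enumerates all chains with exactly one node per stage
and a connectome arc between consecutive nodes, stages resolved
transhierarchically (a stage region matches its whole subtree). Stages
consume single arcs — no multi-hop shortcuts inside a stage — and chains
never revisit a node. Hops carry the ordinal weight, the study count and
a reciprocity flag, because staged circuits are typically read with an
eye on feedback.

## The synthetic generator: what it emulates, what it does not

No machine-readable meso-scale connectome accompanies most curated
analyses, so `generate_connectome()` plants the statistical regime the
pipeline assumes and makes every stage testable offline. Its defaults
are the regime of a condensed intrinsic connectome of a bilateral
forebrain nucleus complex: 49 leaf regions under a depth-8 binary-split
hierarchy, density $464/(49 \cdot 48) \approx 0.197$, three communities
with relative cross-module propensity 0.4, Pareto-tailed (exponent 3)
attachment propensities, and a decreasing ordinal weight distribution
over codes 1–9.

Reciprocity is injected pairwise: each direction has marginal probability
equal to the pair density $d$, and the conditional probability of the
reverse arc given one direction is $d + r(1 - d)$ with
$r = $ `reciprocity_excess` $= 0.6$ by default. This makes the realized
reciprocity exceed the density whenever $r > 0$ while keeping the
expected arc count exactly at the target — and it is precisely the
mechanism that enriches fully reciprocal triads, which the motif
significance stage must detect ($p = 0$ for `3-13` against 200 rewired
nulls in the acceptance suite).

What the generator does *not* emulate: spatial embedding and distance-
dependent wiring costs, correlated laterality structure (all generated
records are ipsilateral), heterogeneous study coverage (every arc gets
one synthetic record), and any particular real adjacency matrix. Passing
tests therefore demonstrate that the *methods* behave correctly on
networks with the assumed statistical structure, not that any biological
claim about a particular species' circuitry is reproduced.

## Null models

Five generators are provided. Erdős–Rényi draws exactly $E$ ordered
pairs uniformly. The rewiring null preserves each node's in- and
out-degree exactly. The classic Watts–Strogatz and Barabási–Albert
models are undirected, so directed adaptations are documented in code:
WS builds a directed ring lattice with arcs both ways round the ring
before per-arc target rewiring; BA attaches each new node with
uniformly random arc direction and total-degree-preferential partner
choice; the Ozik-style growth inserts each new node at a random ring
position and wires it to nearest ring neighbours with alternating
directions (a two-pass fill guarantees the exact arc count). All five
are deterministic under their seed and emit simple digraphs with the
requested node and arc counts. One published generator family defined
only in an external methods paper is deliberately excluded rather than
guessed.

## Numerical choices and degenerate inputs

* Ties in greedy modularity merges break on first index; refinement
  sweep order is the only seeded randomness there.
* `z = 0` by convention for zero-variance motif null distributions;
  single-node graphs report `NA` path length; fewer than three distinct
  valencies report `NA` power-law error; zero-variance PCA features are
  dropped with a warning.
* The rewiring loop caps attempts at 200× the swap target so saturated
  graphs terminate and return a copy.
* All ensemble and Monte-Carlo computations derive per-replicate seeds
  from one master seed, so every artifact of `run_report()` is
  byte-identical across reruns.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at the generator's native 49-node
scale for the motif-significance acceptance check (200 rewired nulls) and
at 5–15 nodes wherever a brute-force oracle (permutation enumeration,
exhaustive partitions, all-geodesic scans, subset classification on 100
random graphs) provides the reference; Monte-Carlo Shapley convergence is
checked at $10^5$ permutations on the 8-node fixture. These sizes were
chosen so each oracle remains exact; the package itself has no such
limits beyond the documented 10-node bound for exact Shapley mode.

## Known limitations

* The ordinal weight vocabulary (which verbal tracer-strength categories
  map to which codes) is corpus-specific and therefore configuration,
  not assertion.
* Exact Shapley mode is bounded at 10 nodes; above that only Monte-Carlo
  estimates (with their sampling error) are available.
* Directed modularity maximization is a heuristic; global optimality is
  only guaranteed where exhaustive search is feasible.
* Motif censuses stop at tetrads; participation scans are quadratic in
  subset count and meant for networks of at most a few hundred nodes.
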