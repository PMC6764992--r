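---
title: "Network Wasserstein metrics, diffusion maps and Mapper: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Wasserstein metrics, diffusion maps and Mapper: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstates)
```

This vignette explains the model behind `netstates`, the assumptions each
stage makes, the tunable parameters and their defaults, and the design
decisions taken where more than one reasonable construction exists. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The problem

Given a non-negative gene-expression quantification matrix (genes ×
samples, FPKM/TPM-like) and a curated gene network — a pathway whose nodes
are genes and whose edges carry optional interaction strengths — we want to
discover, without labels, groups of samples that share a coherent pattern
of gene activation and inactivation, and to see how these groups relate to
one another (a progression, a branching, a cycle). The pipeline has four
mathematical stages, each implemented as an independently testable module.

## Normalization

For display and state calling, each gene row is mapped by the truncated
translated z-score $x \mapsto (x-\mu)/(3\sigma) + 0.5$, clamped to
$[0,1]$. Choices fixed here:

* **σ is the population standard deviation** (divisor $n$). The convention
  must be fixed for exact tests; the population form makes the pre-clamp
  row mean exactly 0.5 and pairs with the Mahalanobis filter's population
  covariance.
* **"Truncated" means hard clamping.** Values beyond $\mu \pm 1.5\sigma$
  map to 0 or 1. Clamping keeps heat maps bounded and is idempotent on the
  unclamped range; rescaling instead would make repeated normalization
  drift. This is an interpretation — the transformation is only promised
  to land "substantially" in $[0,1]$ — and it is deliberately the simplest
  one.
* **Constant genes map to 0.5**: a gene with $\sigma = 0$ carries no
  contrast, and erroring would make whole-matrix normalization fragile.
* Crucially, the **transport metric consumes raw values**, never z-scores:
  the mass interpretation requires non-negativity, and z-scores are signed.
  Normalized values exist only for heat maps and activation calls.

## The network ground metric

The network is an undirected simple graph; directed pathway relations are
flattened, since only the path-length geometry enters the metric. Edge
length is the **reciprocal of the interaction strength** (length 1 where no
strength is given): strong interactions make genes close, so mass moves
cheaply between tightly coupled genes. Repeated edges collapse to the
maximum strength. The ground metric is the all-pairs shortest-path distance
within each connected component. Components are taken as given; no
edge-inference is attempted — a disconnected pathway may reflect missing
knowledge, but guessing edges would silently change the metric.

## Wasserstein-1 distances between samples

A sample's restricted expression vector, divided by its per-component sum
(plus an optional pseudocount), is a probability distribution on each
component's nodes. An alternative construction
(`mode = "invariant_measure"`) uses the stationary distribution of an
expression-attracted random walk: from node $u$ the walker moves to
neighbor $v$ with probability proportional to $x_v + \text{pseudocount}$.
The walk is made lazy (self-loop probability 1/2) so bipartite components
still mix. This construction is this package's own definition of an
expression-derived Markov chain; it concentrates mass on high-expression
neighborhoods rather than on the raw values alone.

Per component, the distance is the optimal value of the transportation
problem $\min_T \sum_{ij} T_{ij}\, g(i,j)$ with marginals $p$ and $q$. The
solver is a **successive-shortest-augmenting-path min-cost flow** with node
potentials on the bipartite supply/demand network, after cancelling the
mass common to $p$ and $q$ (optimal whenever the ground matrix is a metric,
which shortest-path matrices always are). This is the exact continuous-mass
generalization of the assignment formulation: a Hungarian solution applies
only after quantizing mass into equal units, so the package provides
`emd_hungarian()` (largest-remainder quantization + `clue::solve_LSAP`)
purely as a cross-check that converges to the LP value as the unit count
grows. Tests verify the solver against an independent dense-LP oracle
(`boot::simplex`) and against the closed form
$\sum_k |\mathrm{CDF}_p(k) - \mathrm{CDF}_q(k)|$ on unit paths.

Per-component distances amalgamate by the direct sum
$d(s,s') = \sqrt{\sum_c d_c(s,s')^2}$. A component with zero total mass in
*both* samples contributes zero; zero mass in exactly *one* sample is an
error ("incomparable supports"), with the pseudocount (default 0) as the
documented escape hatch — silently imputing a uniform distribution would
fabricate geometry.

Why this metric at all: if two samples carry the same amount of activity in
different places, their Euclidean distance depends only on the amounts,
not on *where* in the network the activity sits. `location_contrast_demo()`
constructs three samples on a path with pairwise-equal Euclidean gaps whose
near-pair Wasserstein distance is half the far-pair distance.

## Diffusion map

The kernel is $W_{ij} = \exp(-d_{ij}^2/\varepsilon)$. Any $\varepsilon$
between the minimum and maximum off-diagonal squared distance is
admissible; the default is their **median**, a robust midpoint; a
user-supplied value outside the range warns rather than errors. The
**α = 1 anisotropic normalization** $\tilde W = D^{-1} W D^{-1}$ (then
row-stochastic $P = \tilde D^{-1} \tilde W$) removes the influence of
sampling density, so the embedding reflects the geometry of the underlying
state space rather than where samples happen to be dense.

Numerics: $P$ is conjugate to the symmetric matrix
$S = \tilde D^{1/2} P \tilde D^{-1/2}$, so the eigenproblem is solved on
$S$ (guaranteed real spectrum, stable `eigen(symmetric = TRUE)`) and
back-transformed. Eigenvalues are ordered $1 = \lambda_1 \ge |\lambda_2|
\ge \dots$; eigenvectors are unit-normalized with the largest-magnitude
entry made positive, a deterministic sign convention that makes embeddings
reproducible across solvers and permutation-equivariant. The trivial
constant eigenvector is dropped before coordinate indexing; explicit
1-based `selected_indices` (e.g. `c(1, 2, 4)`) and an `include_trivial`
flag cover both indexing conventions found in practice. Coordinates are
bare eigenvectors by default; `diffusion_time = t` rescales by
$\lambda^t$ as an extension.

## Mapper

The filter function turns the embedded cloud into an ordered family of
overlapping slices:

* **Closeness centrality** (default): on the symmetrized k-nearest-neighbor
  graph with Euclidean edge lengths, $f(i) = (N-1)/\sum_j d_{\text{graph}}(i,j)$.
  It requires a connected graph; `connected_knn_k()` returns the minimal
  such k, which the pipeline uses by default (`k = "auto"`).
* **Mahalanobis deviation** from a control cohort, with population
  covariance and an optional ridge, when a control set much larger than the
  embedding dimension exists.
* **User-supplied values** (e.g. an experimentally measured progression).

The cover splits $[\min f, \max f]$ into `n_f` base intervals widened by
the overlap fraction $g$ (half of $g\ell$ on each side, clipped to the
range, closed boundaries). $g$ defaults to 0.5, the conventional Mapper
choice; with $g < 1$ every sample lies in one or two bins. Within a slice,
clusters are the single-linkage dendrogram cut at height $t$ — equivalently
the connected components of the distance-$\le t$ graph, which is how the
tests verify it. Clustering happens in the diffusion embedding; that is the
space the Mapper stage is defined on. The nerve has one node per cluster
and an edge between clusters from distinct bins sharing at least
`min_overlap` samples (default 1; the overlap count is recorded on the
edge). 2-simplices can be recorded behind a flag.

No automatic $(n_f, t)$ selection is attempted: `scan_parameters()`
tabulates node/edge/component counts over a grid and flags the two
degenerate regimes (all singletons; one merged cluster), and
`pick_stable_parameters()` deterministically returns the middle row of the
connected non-degenerate band when a script needs a reproducible choice.
The pipeline's default $t$ (half the median pairwise embedding distance) is
a starting point for exploration, not a tuned value.

## State graph and activation calls

Nodes of degree ≥ 3 and isolated nodes are breakpoints; edges split into
maximal simple paths with degree-2 interiors. A component that is a pure
cycle has no breakpoint; it is cut at its smallest node id and flagged as a
cycle rather than silently linearized. Paths are ordered by total sample
count (largest first — the "core"; ties by smallest node id), making the
decomposition deterministic. Samples are ordered path by path, within each
node ascending by filter value (ties by id), first occurrence kept.

The default state grouping is one group per maximal path, with per-path
filter extremes reported as metadata (states tend to be clearest near the
filter's extremes); callers may pass any named node subsets instead. Per
group and gene, the mean normalized value $\bar v$ yields the call:
activated if $\bar v \ge 0.5 + \delta$, inactivated if
$\bar v \le 0.5 - \delta$, else equivocal, with closed boundaries.
**δ defaults to 1/6**, which is half a raw standard deviation on the
$(x-\mu)/(3\sigma)+0.5$ scale — a gene must sit half a σ away from its
cohort mean, on average within the group, to be called.

## Synthetic data: what it emulates and what it does not

The generator plants $k$ named activation patterns over a small network
(path, star, two-community, or seeded random tree). Each gene has a level
per state — high, low, or mid, with mid at the geometric mean of high and
low so its z-score sits near 0.5 — and samples are drawn as
$\text{mean} \times \exp(\sigma_{\text{noise}} z)$, multiplicative
log-normal noise matching the positivity and right skew of FPKM/TPM data.
The default design is 3 states × 30 samples on a 12-gene path with high/low
means 10/1, $\sigma_{\text{noise}} = 0.2$, seed 7; the default states are
equal-sized high blocks in different network locations, so states differ
*only* by where their activity sits. `interpolated_branch()` adds bridge
samples along convex combinations of state means 1–2 and 1–3 (8 per arm by
default), a Y-shaped cloud whose correct state graph has exactly one branch
node.

These data exercise every contract of the pipeline but are far easier than
real cohorts: no batch effects, no dropout, no correlated noise across
genes, no partial or wrong network edges, and states that are genuinely
well separated. Passing the planted-recovery checks shows the machinery is
correct, not that real tissue cohorts will separate as cleanly.

Problem sizes used by the test suite and acceptance script — networks of
6–12 genes, 90–106 samples, 100–200 random transport instances — were
chosen so the whole validation runs in a few minutes while still exercising
multi-component networks, degenerate slices, cycles and branches.

## Known limitations

* Single-gene perturbations can move a sample disproportionately: all of
  one gene's mass shift is charged the full ground distance.
* The package does not parse pathway databases (KEGG KGML etc.); networks
  arrive as plain edge lists, and non-gene pathway nodes (compounds,
  complexes) are out of scope, so a gene-only projection of a richer
  pathway loses information by construction.
* Directed regulation semantics (activation vs inhibition signs) are not
  modelled.
* The Mapper summary depends on $(n_f, t)$; the scan utility exposes, but
  does not remove, that dependence.
* No out-of-sample extension: adding a sample means recomputing the
  distance matrix and embedding.
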