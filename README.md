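# netstates

Unsupervised discovery of coherent transcriptomic states ("molecular
phenotypes") from a gene expression matrix and a gene network.

Bulk and single-cell RNA-Seq experiments yield non-negative quantification
matrices (FPKM/TPM-like) over thousands of genes. When the question is how
samples organize along a *known pathway* — which groups of samples share a
consistent pattern of activated and inactivated genes — ordinary clustering
on Euclidean distances ignores everything the pathway structure says about
which genes influence which. `netstates` implements a pipeline for exactly
this setting, aimed at computational biologists analysing cohorts of tissue
or cell samples against curated networks:

1. **Network Wasserstein metric.** Each sample's expression vector,
   restricted to the network's genes and normalized to total mass 1 per
   connected component, is a probability distribution on the network's
   nodes. Two samples are compared by the Wasserstein-1 (Earth Mover's)
   distance

   d_c(s, s′) = min over transport plans T of Σᵢⱼ Tᵢⱼ · g(i, j),

   where g is the shortest-path ground metric (edge length = 1/strength),
   amalgamated across components c by the direct sum
   d(s, s′) = √( Σ_c d_c(s, s′)² ). Mass that must travel far through the
   network costs more, so samples whose activity sits in distant parts of
   the pathway are far apart even when their Euclidean gap is identical to
   that of a near pair.
2. **Diffusion map.** The metric space is embedded via the Gaussian kernel
   W = exp(−d²/ε) with the anisotropic (α = 1) normalization
   W̃ = D⁻¹WD⁻¹, P = D̃⁻¹W̃; selected nontrivial eigenvectors of P are the
   sample coordinates.
3. **Mapper.** The embedded cloud is sliced into overlapping filter bins
   (default filter: k-nearest-neighbor closeness centrality), each slice is
   single-linkage clustered at threshold t, and the nerve of the clusters is
   the **state graph**.
4. **States.** The graph's 1-skeleton is decomposed into maximal linear
   paths (core and branches); samples are ordered along the paths by filter
   value, and per path each gene is called activated (mean normalized
   expression ≥ 0.5 + δ), inactivated (≤ 0.5 − δ) or equivocal, on the
   truncated translated z-score scale x ↦ (x − μ)/(3σ) + 0.5 clamped to
   [0, 1].

The Wasserstein solver (successive shortest augmenting paths on the
transportation network) is exact; tests validate it against an independent
LP oracle, a closed form on path graphs, and a quantized Hungarian
assignment.

## Worked example

The package ships a seeded generator that plants coherent states on a toy
network. Three states on a 12-gene path, each active (raw mean 10 vs 1,
log-normal noise σ = 0.2) in a different third of the path, 30 samples per
state:

```r
library(netstates)

ds  <- generate(planted_design())          # expression + network + labels
res <- run_pipeline(list(expression = ds$expression,
                         network    = ds$network,
                         outdir     = "demo_out"))

res$distance
#> <sample_dist> 90 samples; range [0, 6.768]
res$embedding
#> <diffusion_map> 90 samples, 2 coordinate(s); |lambda| = 1.0000, 0.7534, 0.3101, 0.0039 ...
res$stategraph
#> <state_graph> 13 nodes, 9 edges, 4 path(s), 0 branch node(s)
head(res$calls[res$calls$call == "activated", ], 4)
#>    state gene      call      mean
#> 9  path1  g09 activated 0.9292287
#> 10 path1  g10 activated 0.9106489
#> 11 path1  g11 activated 0.9152530
#> 12 path1  g12 activated 0.9086695
```

The two informative eigenvalues (0.75, 0.31) reflect the two directions
separating three states. The state graph splits into per-state chains of
Mapper nodes; `path1` collects the samples of the state active in genes
g09–g12, and those genes are the ones called activated with mean normalized
expression near 0.93. Comparing the path grouping with the hidden labels
gives an adjusted Rand index of 0.98, and every planted activation pattern
is recovered exactly at the default δ = 1/6.

Every intermediate (restricted and normalized matrices, distance matrix,
embedding, Mapper complex, state graph, sample order, state calls, display
matrices, manifest) is written under `outdir`. A command-line front end
over the same functions is installed at
`system.file("scripts/netstates", package = "netstates")` with subcommands
`synth`, `run`, `scan`, `normalize`, `restrict`, `distance`, `diffuse`,
`mapper`, `states`.

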