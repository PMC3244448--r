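# spanet

Reconstruction, statistical tuning and path-based dissection of
process-specific protein–protein interaction networks.

## What it does, and for whom

Interaction databases describe an organism's whole interactome; a study of
one cellular process (the motivating case is the chronological aging of
quiescent yeast) needs the context-specific slice of it.  `spanet` is for
systems biologists who want that slice carved out reproducibly from an
edge list, a GO annotation table and a list of core proteins, and then
dissected down to the proteins that carry the signal flow:

1. **Selective-permissibility reconstruction.**  Starting from core
   proteins (those annotated to the process), the network is expanded
   through physical interactors.  A candidate joins iff its GO annotations
   in all three aspects (process / function / component) fall inside the
   *annotation collection* pooled from the core proteins — with the three
   root "unknown" terms always admissible, so lack of curation never
   excludes a protein.  Expansion iterates to a fixed point and returns
   the induced subgraph.
2. **Betweenness tuning.**  Each node's shortest-path betweenness
   centrality BC(v) is compared against its values in R = 100
   degree-preserving edge-shuffled random networks (double-edge swaps,
   skewness control chart on the ensemble).  A dependent two-tailed paired
   t-test on dᵢ = BCobs − BCnull,i with R−1 df discards nodes with
   p ≥ α (default α = 0.001): nodes whose contribution to information flow
   is indistinguishable from random are removed with their interactions.
3. **Topology.**  P(k) ~ k^−γ and C(k) ~ k^−w by log–log OLS (raw
   histograms), ⟨k⟩, mean shortest path, diameter, ⟨CC⟩, hubs, and
   connected-component impact of hub deletion.
4. **Linear paths.**  Exhaustive enumeration of simple paths of exactly
   L = 6 nodes (input, 4 intermediates, output) between configured
   input/output pairs, with per-pair path counts, protein unions, unique
   proteins, core protein coverage (CPC) and overall protein coverage
   (OPC).
5. **Step-specific key proteins.**  Per intermediate position, the
   participation frequencies are binned into k = round(√n) equal-width
   bins; with cumulative percentages Mᵢ and increments Dᵢ, the fold change
   Fᵢ = Dᵢ/Dᵢ₊₁ selects the threshold bin (largest Fᵢ whose strict tail
   holds ≤ 10% of proteins) and proteins above it are the step's keys,
   used as baits to filter the paths before the next position is
   decomposed.  Pooling all branches' keys with the endpoints gives the
   condensed "heart" network, with per-branch path coverage.

A first-class synthetic-data module generates seeded annotated
interactomes with planted ground truth (an exactly recoverable admissible
region; backbone/decoy path corridors), so the entire pipeline is testable
offline.

## Worked example

```r
library(spanet)

dir <- file.path(tempdir(), "fx")
simulate_fixture(dir, seed = 1)          # 300-protein synthetic fixture
fx  <- read_fixture(dir)

rec <- spa_expand(fx$core, fx$graph, fx$annotations)
rec$log
#>   iteration candidates admitted rejected ... cumulative_nodes
#> 1         1         59       51        8 ...               57
#> 2         2        153      137       16 ...              194
#> 3         3         83       74        9 ...              268
#> 4         4         11        6        5 ...              274
#> 5         5          0        0        0 ...              274
identical(rec$members, sort(fx$truth$admissible))
#> [1] TRUE

tn <- tune_network(rec$network, alpha = 0.001, n_random = 100, seed = 1,
                   protect = unlist(fx$pairs))
topology_summary(tn$network)
#> <topology_summary> 173 nodes, 253 edges, <k> = 2.92, CPL = 3.95, d = 9, <CC> = 0.046
#>   P(k) ~ k^-1.58 (R^2 = 0.86)
#>   C(k) ~ k^-0.42 (R^2 = 0.21)

sp <- enumerate_paths(tn$network, fx$pairs[1, 1], fx$pairs[1, 2], L = 6)
sp
#> <path_spectrum> P0002 -> P0009, L = 6: 6 paths
sk <- stepwise_keys(sp)
heart <- assemble_heart(list(sk), fx$pairs[1, 1], fx$pairs[1, 2],
                        tn$network, spectra = list(sp))
heart
#> <heart_network> 13 proteins, 20 interactions
#>   path coverage: 100.0-100.0% across 1 branches
```

Reading the numbers: the 6 core proteins expand to a 274-node network in
four admission cycles (the fifth admits nobody — the fixed point), exactly
matching the generator's planted admissible region.  Tuning at α = 0.001
removes ~37% of nodes as statistically indistinguishable from the
degree-preserving null; the surviving network keeps the heavy-tailed
degree regime (γ ≈ 1.6, R² = 0.86).  Between the first configured
input/output pair there are 6 six-node signaling routes, whose stepwise
decomposition condenses into a 13-protein heart network covering 100% of
the routes.

The orchestrated equivalent is one call — `run_pipeline(pipeline_config(...))`
— which writes every stage's tables (TSV/GraphML/JSON) plus a manifest
with parameters, seeds and output digests; a thin command-line wrapper
lives at `inst/scripts/spanet-pipeline.R`.

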