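# metanet

Evolutionary analysis of bipartite metabolic networks in R.

Modern metabolism grew by **enzyme recruitment**: structural domains of
ancient enzymes were coopted into new pathways and specialized there. Given
an integrated table of enzymes (EC numbers), their KEGG pathway memberships
("subnetworks", grouped into 11 "mesonetworks"), their SCOP fold-family
domains and each family's phylogenomic age *nd* ∈ [0, 1] (0 = most
ancient), `metanet` reconstructs how the metabolic network unfolded in
time and measures the organizing principles of that growth. It is written
for systems/evolutionary biologists who want the full pipeline — data
model, networks, statistics, recruitment analyses — as tested, scriptable
functions rather than a one-off analysis.

## What it computes

An enzyme's age is the *nd* of its **second oldest** domain (a cooption
needs an old donor and an acceptor; `rule = "oldest"` is the alternative).
Slicing the category–enzyme bipartite graph `B` at thresholds
t = 0.1, …, 1.0 yields a growing network series; each slice is decomposed
into its weighted one-mode projections (edge weight = number of shared
counterpart nodes). Per slice and per graph, the battery reports:

* discrete power-law fit of the degree sequence — zeta-normalized MLE with
  KS-minimizing `xmin` and a seeded semi-parametric bootstrap p-value
  (scale-free band: 2 < α < 3);
* Bartels rank von Neumann randomness test,
  RVN = Σ(Rᵢ−Rᵢ₊₁)² / Σ(Rᵢ−R̄)², E[RVN] = 2 under exchangeability, Beta
  approximation p-values, plus the same test on a matched Erdős–Rényi
  graph;
* small-world coefficient S = (C_g/C_rand)/(L_g/L_rand) against a seeded
  G(n, m) ensemble;
* maximum fast-greedy (Clauset–Newman–Moore) modularity Q;
* hierarchical-modularity scaling C(k) ~ k⁻¹ (log–log OLS slope and r²);
* degree / betweenness / closeness centralities with top-k tables;
* recruitment views: subnetwork × era sharing matrices, mesonetwork link
  tables, classic-Ward dendrograms (squared Euclidean distances) with
  scaled modularity-matrix heatmaps, superkingdom Venn groups (with the
  EC-revision consensus rule), functional and catalytic-site
  distributions.

A seeded synthetic-data generator (`simulateDataset()`) emulates the real
data's statistical structure — 11 mesonetworks, ~148 subnetworks, 1,900
enzymes, multidomain enzymes, age-coupled cross-pathway sharing, and the
biphasic domain-age distribution (peaks in eras 1 and 6–8) — so the whole
pipeline is testable without any external download. See the methods
vignette (`vignettes/evolving-metabolic-networks.Rmd`) for every model
choice and its rationale.

## Worked example

```r
library(metanet)

# a multidomain enzyme with domain ages as printed for EC 4.2.1.17:
assignEnzymeAge(c(0.791971, 0.0912409, 0.080292, 0.0912409, 0.813869))
#> [1] 0.0912409        # the second oldest domain dates the enzyme

ds   <- simulateDataset(simulationConfig(seed = 1))
ds
#> MetabolicDataset
#>   enzymes:            1900
#>   subnetworks:        167
#>   mesonetworks:       11
#>   domain assignments: 3431
#>   membership links:   3404
#>   annotations:        taxa, functions, catalysis

ages <- enzymeAges(ds)                        # second-oldest rule
B    <- buildBipartite(ds, ages, "subnetwork")
enz  <- projectOneMode(sliceByAge(B, 1.0), "enzyme")
smallWorld(enz, nRand = 10, seed = 1)
#> Small-world comparison (LCC n = 1900, m = 44142, 10 ER replicates)
#>   C_g = 0.7971  C_rand = 0.0244  gamma = 32.642
#>   L_g = 2.7221  L_rand = 2.2885  lambda = 1.189
#>   S = 27.443
```

The enzyme projection is strongly small-world (S ≫ 1): clustering ~33×
an equivalent random graph at nearly the same path length — pathway
co-membership makes enzymes cluster into overlapping cliques. Running
`metricsTimeline(ds, ages)` produces the full 30-row battery (3 graph
types × 10 thresholds); on this synthetic dataset the enzyme projection's
mean clustering rises monotonically along the timeline, the evolving-
cohesiveness trend the pipeline is designed to expose.

The end-to-end run (dataset → slices → battery → recruitment →
annotation tables, all as diffable TSVs plus a YAML manifest):

```r
runTimeline(runConfig(outDir = "run1", seed = 1))
```

or from a shell: `Rscript inst/scripts/metanet.R all --seed 1 --out run1`.
Two runs with the same seed are byte-identical.

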