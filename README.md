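# myconet

Plant–fungus bipartite interaction networks from root mycobiome
metabarcoding tables.

## What it does

Root-sample metabarcoding yields read-count tables (samples × fungal
OTUs) with plant-host metadata. `myconet` takes such tables through the
full interaction-network pipeline used in root mycobiome studies:

1. **Guild filtering** — keep putatively mycorrhizal OTUs via a lineage
   whitelist; drop samples with < 20 retained reads.
2. **Interaction calling** — a cell (sample, OTU) is an interaction iff
   it holds ≥ 5 reads *and* ≥ 1% of the sample's reads.
3. **Network construction** — species-level binary, abundance
   (per-thousand compositions) and incidence (supporting-sample counts)
   networks per fungal lineage and community.
4. **Structure** — connectance, checkerboard score (C-score), binary
   nestedness NODF2, weighted NODF, and Barber bipartite modularity
   `M = (1/m) Σ_within (A_ij − k_i d_j / m)` with its within-module
   interaction ratio Q, maximized by a label-propagation + greedy-merge
   optimizer.
5. **Specialization** — normalized degree, Blüthgen's
   `d′ = (d − d_min)/(d_max − d_min)` with
   `d = Σ_j p′_ij ln(p′_ij/q_j)`, and the network-level
   `H2′ = (H2max − H2)/(H2max − H2min)`.
6. **Significance** — quasiswap-type fixed-marginal nulls, Patefield
   marginal nulls, and a shuffle-sample null that permutes species
   labels and rebuilds the network; two-tailed 2.5% decisions plus
   `(x+1)/(n+1)`-corrected p-values.
7. **Motifs** — exhaustive census of connected bipartite subnetworks
   (2–6 nodes, 44 canonical classes), node positions as automorphism
   orbits, and PCoA of motif-frequency profiles.
8. **Composition** — Bray–Curtis dissimilarities, single-factor
   PERMANOVA, PCoA, neighbor-joining dendrograms.
9. **Synthetic data** — `make_scenario()` / `simulate_reads()` generate
   read tables with planted nested, modular or random structure,
   sequencing-depth heterogeneity, Dirichlet compositional noise,
   Poisson contamination and sample-specific rare OTUs.

## Worked example

```r
library(myconet)

# a synthetic community with three planted plant-fungus modules
truth <- make_scenario("modular", seed = 11)
tab   <- simulate_reads(truth, seed = 12)
tab
#> sample_table: 72 samples x 46 OTUs (18S), 12 plant species, 653,657 reads

ft  <- filter_guild(tab, guild_config("Glomeromycotina", min_sample_reads = 20))
net <- build_network(ft, "binary")
net
#> bipartite_network (binary): 12 plant species x 40 OTUs, 154 links, community community1

connectance(net)
#> [1] 0.3208333

part <- optimize_modules(net, restarts = 10, seed = 5)
part
#> module_partition: 3 modules, M = 0.6015, Q = 0.9351

null_test(net, "modularity", "quasiswap", n_null = 50, seed = 3,
          optimizer_args = list(restarts = 2))
#> null_test: modularity = 0.6015 vs quasiswap null (n = 50)
#>   p_upper = 0.01961, p_lower = 1 [significantly HIGH]
```

The recovered partition has modularity M = 0.60 with 94% of
interactions inside modules (Q), and exceeds every fixed-marginal null
draw — the planted modular structure is real, not a marginal-totals
artifact. The same calls work on loaded data
(`load_sample_table(counts.tsv, meta.tsv, tax.tsv)`).

A thin command-line wrapper over the same functions ships in
`inst/cli/myconet.R`:

```sh
Rscript inst/cli/myconet.R simulate --structure modular --seed 1 --out scratch/demo
Rscript inst/cli/myconet.R structure --counts scratch/demo/counts.tsv \
  --meta scratch/demo/sample_meta.tsv --tax scratch/demo/taxonomy.tsv \
  --whitelist Glomeromycotina --net-type binary --seed 1
```

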