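---
title: "Plant-fungus bipartite networks from root mycobiome tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant-fungus bipartite networks from root mycobiome tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myconet)
```

## The problem

Root mycobiome metabarcoding produces sample-level OTU read-count
tables: each root sample of a known plant species yields read counts
over fungal OTUs, for one marker (18S rRNA for Glomeromycotina and
Mucoromycotina; ITS2 for Sebacinales, Helotiales and Cantharellales).
The scientific questions live one level up: which plant species share
which fungi, how nested or modular the species-level interaction
networks are, how specialized each plant is toward its fungal
partners, and whether any of this exceeds what sampling noise and
species abundances alone would produce. `myconet` implements that
pipeline: guild filtering, interaction calling, network construction,
structure and specialization statistics, permutation null models,
motif censuses, and sample-level compositional analyses, plus a
synthetic generator with planted ground truth so every stage can be
validated without any sequencing data.

## From reads to interactions

Two thresholds turn counts into interactions, and both must hold for
a cell (sample, OTU):

* **contamination floor**: at least 5 reads (`min_reads`); low-level
  cross-sample contamination typically leaves a handful of reads;
* **relative rule**: at least 1% of the sample's reads
  (`rel_threshold = 0.01`), which corrects for heterogeneous
  sequencing depth.

The denominator of the relative rule is by default the sample's total
in the table passed to `detect_interactions()`. When networks are
built per fungal lineage, pass `sample_totals` from the full
guild-filtered table so that "1% of the reads of the root sample"
refers to the whole sample rather than the lineage subset; both
conventions are exposed because the lineage-subset denominator is the
stricter, defensible alternative.

Upstream of interaction calling, `filter_guild()` keeps OTUs whose
lineage path matches a user-supplied whitelist (the package does not
bundle a guild annotation tool; the whitelist is declarative) and then
drops samples with fewer than 20 retained reads (`min_sample_reads`),
below which a sample's composition is mostly noise.

## Species-level networks

`build_network()` aggregates samples by plant species within one
community (plots are merged; keep them separate by subsetting if the
plot effect is of interest) into three network types: **binary**
(detected in at least one sample), **incidence** (number of samples
supporting the interaction, bounded by the species' sample count),
and **abundance** (reads per thousand over the species' detected
cells, so each row is a composition summing to 1000). The abundance
denominator uses detected-cell reads only; reads in cells that failed
detection never contribute. All-zero rows and columns are pruned, and
networks with fewer than two plants or two OTUs are refused: every
downstream statistic is undefined there.

## Structure statistics

* **Connectance**: realized fraction of possible links.
* **C-score**: mean checkerboard units over plant pairs,
  `(r_i - S)(r_j - S)`; computed over plant rows by default because
  the question is partner avoidance among plants (`axis = "cols"`
  switches sides).
* **NODF2**: rows and columns are first sorted by decreasing degree;
  an ordered pair with strictly decreasing degree contributes the
  percentage of the poorer node's partners shared with the richer
  one; equal degrees contribute exactly 0 (the standard
  decreasing-fill rule), with a stable sort so ties keep their input
  order and results are reproducible.
* **Weighted NODF**: same construction on marginal totals, counting
  cells where the poorer row's positive weight is strictly smaller
  than the richer row's. Sorting is applied in both the binary and
  weighted variants.
* **Barber modularity**: `M = (1/m) * sum_within (A_ij - k_i d_j/m)`,
  maximized by `optimize_modules()` - label propagation between the
  two sides followed by greedy module merges, with random restarts
  (default 20) and deterministic seed substreams. One optimizer
  serves binary and weighted objectives: the two published algorithms
  it replaces are both maximizers of the same modularity surface, and
  what is validated here is planted-structure recovery, not algorithm
  identity. Weighted modularity uses the raw abundance weights
  (per-thousand) without rescaling; `m` is the analyzed matrix's
  grand total. `Q`, reported alongside `M`, is the fraction of
  interaction weight falling within modules.

## Specialization

Specialization uses the abundance network (incidence networks carry
too little weight information). For plant `i` with row total `A_i`,
partner use `p'_ij = a_ij / A_i` and availability `q_j = C_j / m`:

* `d_i = sum_j p'_ij ln(p'_ij / q_j)` (nats; natural logarithms
  throughout, the Bluthgen convention);
* `d'_i = (d_i - d_min) / (d_max - d_min)` with `d_max = ln(m / A_i)`
  and `d_min` from redistributing `A_i` integer units over fungi
  proportionally to `q` by largest-remainder apportionment; values
  are clipped to [0, 1] and a degenerate denominator yields 0 with a
  warning.
* `H2' = (H2max - H2) / (H2max - H2min)`, where `H2` is the Shannon
  entropy of the whole matrix and the extrema are heuristic solutions
  over non-negative integer tables with the observed marginals:
  `H2max` from the floor of the independence table repaired by
  largest remainders under marginal needs, `H2min` by greedily
  packing the largest feasible value into the currently largest
  row x column cell. On small tables these heuristics reach the
  exhaustive-search extrema exactly (validated over all 3x3 tables
  with marginals (3,3,3)/(3,3,3)); real-valued abundance weights are
  rounded to integer pseudo-counts first, which leaves `d'` and `H2'`
  stable under exact integer rescaling up to heuristic granularity.

## Null models and significance

Three permutation ensembles, with the pairings used throughout
(`default_null_pairings()`):

* **quasiswap-type fixed-fixed null**: uniform over binary matrices
  with the observed row and column sums (fill is implied by the
  marginals). Draws are produced by a burned-in, thinned curveball
  trade chain (burn-in 30x fill, thinning 2x fill): the target
  distribution is the one the classical quasiswap algorithm samples,
  but trade chains remain fast when skewed marginals force rows or
  columns, the regime where swap-repair samplers stall. The count
  variant preserves row sums, column sums, grand total and fill.
* **Patefield (marginal) null**: uniform contingency tables with the
  observed marginals, free fill; used for the specialization indices.
  For abundance networks the marginals are the integer-rounded
  per-thousand weights, a documented granularity caveat.
* **shuffle-sample null**: permutes the species labels of the root
  samples within a community and rebuilds the network from scratch,
  testing whether species-level patterns exceed what sample identity
  alone produces.

`null_test()` reports both one-tailed p-values with the
`(x + 1)/(n + 1)` at-least-as-extreme correction, and significance
flags that follow the raw two-tailed 2.5% rule (at most 2.5% of null
values greater-or-equal, respectively less-or-equal, than the
observed); both are reported because the correction is the defensible
p-value while the raw rule is the field's decision convention.
Replicates derive from seed substreams, so results do not depend on
evaluation order. The default ensemble size is 10,000.

A structural caveat worth knowing: binary NODF2 against the
fixed-fixed null is conservative by construction. A perfectly nested
support is the *unique* binary matrix with its marginals, so every
null draw ties the observed value, and partially nested supports
score at or below the null mean because uniform fixed-marginal
matrices with skewed marginals are themselves strongly nested. Power
against nestedness comes from the weighted NODF under the count null,
where the weight arrangement carries information beyond the support
marginals - which is how the nested-recovery validation is framed.

## Motifs

`motif_census()` counts connected induced subnetworks of 2-6 species
against a self-defined canonical dictionary (sizes 2:6 hold 1, 2, 4,
10 and 27 classes; 44 in total). Plant and fungus sides are never
interchanged. The canonical key of a bi-adjacency matrix is the
lexicographically smallest row-major bit string over degree-sorted row
orders with columns sorted ascending; the dictionary carries a
`published_id` cross-walk slot because external motif numberings
differ and are not replicated blindly. Node positions are automorphism
orbits, computed exactly by permutation search. Enumeration uses the
ESU connected-subgraph algorithm; it is exhaustive and exact, sized
for networks up to roughly 60 nodes at `max_nodes = 6` (use
`max_nodes = 5` or 4 for larger networks). Motif-frequency profiles
are compared across networks by PCoA after `sum_all` normalization
(Bray-Curtis distance by default).

## Composition layer

Bray-Curtis dissimilarities are computed on per-sample relative
abundances by default (raw counts optional, since the choice is not
fixed by convention). PERMANOVA is single-factor with unrestricted
permutations (the factors of interest - community, plot, taxonomic
group - are tested one at a time), delegating the pseudo-F
computation to the standard distance-based ANOVA partition with
10,000 permutations by default. PCoA is classical scaling; negative
eigenvalues, expected under Bray-Curtis, are dropped from the
coordinates but reported. Dendrograms use Saitou-Nei neighbor joining
and serialize to Newick; negative branch lengths are kept unless
clamped, so additive inputs round-trip exactly.

## The synthetic generator

`make_scenario()` + `simulate_reads()` emulate the structure of a
root-sampling study: communities x plots x plant species (labelled
with the seven plant taxonomic groups) x samples per species, a
fungal OTU pool for one lineage, and a planted plant x OTU propensity
matrix:

* **nested**: a triangular core (`rank_i + rank_j <= nest_span`,
  plus the top OTU for every species) with Bernoulli cell flips at
  rate `nest_noise` - holes inside the core, sporadic links outside
  it. At `nest_noise = 0` the support is exactly triangular; the
  default noise (0.15) leaves a detectably nested but imperfect
  network. The default span (0.7) puts the core connectance near
  0.25, inside the 0.14-0.34 range reported for real root mycobiome
  networks; the earlier full-triangle alternative gave connectance
  above 0.5 and a generalist row linked to every OTU, which is both
  unrealistic and degenerate for fixed-marginal nulls. `alpha`
  (default 2) skews weights toward the generalist corner.
* **modular**: species and OTUs split into `n_modules` (3) blocks;
  links with probability `p_in = 0.9` within and `p_out = 0.05`
  between blocks, gamma-distributed weights.
* **random**: i.i.d. Bernoulli(0.3) links with gamma weights - the
  calibration case.

Reads per sample: expected composition = propensity row x community
availability (mild log-normal heterogeneity per community), perturbed
by a Dirichlet draw with concentration 50 (sample-to-sample
variability of the kind real root samples show), log-normal depth
(log-mean 9 ~ 8100 reads, log-sd 0.5), multinomial reads.
Contamination injects on average 3 foreign-OTU cells per sample with
Poisson(2) reads each, designed so the 5-read floor removes them at
the Poisson-tail rate; sample-specific rare OTUs are injected at rate
0.05 per sample. Every sample uses its own seed substream, so
generation is order-independent and deterministic.

What the generator does *not* emulate: sequence-level artifacts (PCR
bias, chimeras), marker-specific amplification differences beyond a
per-lineage multiplier, phylogenetic signal among OTUs, and spatial
autocorrelation between plots. Passing validation on synthetic data
therefore demonstrates correctness of the statistical machinery under
a known generative model, not robustness to every artifact of real
metabarcoding data.

## Validation scale and numerical choices

The test suite validates each statistic against independent
brute-force oracles (pairwise loops, exhaustive subset enumeration
with permutation-search isomorphism, exhaustive integer-table
enumeration) on matrices up to 8x8 (structure metrics), networks up
to 14 nodes (motifs), and full synthetic pipelines at 12 species x
40 OTUs x 6 samples (recovery: planted modules at adjusted Rand
index >= 0.9 and >= 90% significant modularity; planted nestedness
>= 90% significant weighted NODF; ~5% two-tailed false positives on
unstructured scenarios over 200 runs with 199 nulls each). These
sizes were chosen as the smallest at which the planted effects are
comfortably identifiable. Ties in NODF sorting break by original
order; module optimization accepts only strictly positive gains
(tolerance 1e-12); H2' denominators below 1e-12 define H2' = 1
(single-cell networks) or 0 (degenerate d'), each with a message or
warning.
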