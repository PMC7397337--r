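---
title: "SOM portrayal of SNP genotype landscapes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM portrayal of SNP genotype landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`snpsom` portrays genome-wide biallelic SNP panels as per-accession
landscape images and derives population-structure, phenotype and
pseudotime analyses from them. This vignette is the package's account of
the underlying models, the parameters that matter, and the choices made
where the design was genuinely open.

## The eMAF score

For each SNP, genotypes are coded 0 (homozygous major), 1 (heterozygous),
2 (homozygous minor). With genotype-class fractions $p_{AA}, p_{het},
p_{aa}$, the minor allele frequency is $\mathrm{MAF} = p_{aa} +
p_{het}/2$, so the mean code equals $2\,\mathrm{MAF}$. The SNP-score

$$\text{score} = \text{code} - 2\,\mathrm{MAF}$$

is the per-SNP mean-centered code: $-2\mathrm{MAF}$, $1-2\mathrm{MAF}$ and
$2(1-\mathrm{MAF})$ for the three classes. Averaging scores over any SNP
set $S$ in one accession $m$ gives
$\langle \text{score}\rangle_{S,m} = 2(\mathrm{MAF}_{S,m} -
\langle\mathrm{MAF}\rangle_S)$ — the *excess* minor allele frequency
(eMAF) of that SNP set in that accession relative to the panel. Positive
values mean the accession is enriched for the minor alleles of $S$.

Decisions taken here:

* **Orientation.** SNPs whose upward-coded allele frequency exceeds 0.5 are
  flipped ($c \to 2-c$) so MAF $\in [0, 0.5]$. An exact 0.5 tie keeps the
  input orientation (deterministic; a warning is raised).
* **Missing genotypes** are mean-imputed, i.e. scored 0: they contribute no
  evidence in either direction and row centering is preserved. Frequencies
  are computed over observed genotypes only.
* **Monomorphic SNPs** score 0 everywhere and are kept by default; they
  cannot influence the self-organization but occupy units, so
  `drop_monomorphic()` (and the pipeline's `drop_monomorphic` flag) can
  remove them.

## Batch SOM training

`train_som()` clusters the SNP score *profiles* (rows: one value per
accession) onto a rectangular `grid_rows x grid_cols` lattice of unit
weight vectors ("meta-SNPs"), minimizing Euclidean distance. The default
50 × 50 grid yields K = 2500 units, roughly 4 SNPs per unit on a
10,000-SNP panel — coarse enough to denoise, fine enough to separate
modules.

Training is the deterministic *batch* algorithm: per epoch, every SNP maps
to its best-matching unit (BMU; ties broken toward the lowest unit index),
then every unit weight is replaced by the Gaussian-neighborhood-weighted
mean of the mapped profiles. The neighborhood radius decays linearly from
`max(grid dims)/2` to `radius_final = 1` over `epochs = 20`. Weights are
initialized on the plane of the first two principal components of the
profile cloud, so training is reproducible without randomness (`init =
"random"` is available and seeded). These schedule values are standard SOM
practice at this grid occupancy; the method is insensitive to moderate
changes and all of them are exposed.

Numerical notes:

* The per-epoch quantization error (mean distance of each profile to its
  BMU) is logged; under the decaying-radius batch schedule it decreases
  monotonically in practice, and the tests assert it.
* Units that attract no SNPs keep Gaussian-interpolated weights — this is
  what makes the portraits smooth landscapes rather than sparse dot plots.
* Unit weights are *neighborhood-smoothed* member means. With the final
  radius of 1 the adjacent-unit kernel weight is ~0.61, so a unit's weight
  is close to, but not equal to, the plain mean of its member SNP scores;
  agreement is strong in aggregate (the tests check rank agreement at the
  population level), and the exact algebraic identity asserted is the
  kernel-weighted one.

A portrait (`portrait()`) is one accession's column of unit weights shaped
onto the grid (row-major); group portraits (`mean_portrait()`) average
member portraits element-wise.

## Spot segmentation

`spot_segmentation()` builds a summary grid — by default the per-unit
*maximum* over portraits, the most inclusive deterministic summary of
"red" over-representation (mean and 90%-quantile summaries are exposed) —
thresholds it at its `q_high = 0.98` quantile, and keeps 8-connected
components of at least `min_size = 4` units as spots, lettered A, B, … in
row-major centroid order. Only positive regions are segmented; blue
valleys are background. The thresholds are configuration, not constants:
the spot count on any given panel is threshold-dependent.

Spot statistics (`spot_profiles()`): the spot profile is the mean eMAF
over member units per accession; an accession *calls* a spot when that
profile exceeds the accession's own `call_quantile = 0.98` portrait
quantile (each accession is its own reference, so globally "hot"
accessions do not call everything); the spot count is the number of calls;
the entropy is the base-2 Shannon entropy of the non-negative,
renormalized spot profile (all-nonpositive profiles define entropy 0 — the
formula was an open choice, this one is scale-free and bounded by
$\log_2 n_{spots}$). Spot-spot similarity uses Pearson correlation and the
signed weighted topological overlap
$\omega_{ij} = (\sum_{k \ne i,j} a_{ik}a_{kj} + a_{ij}) /
(\min(k_i,k_j) + 1 - |a_{ij}|)$ with $k_i = \sum_{k\ne i} |a_{ik}|$;
implication graphs connect spots whose call vectors have Jaccard index
$\ge \tau = 0.25$.

## Phenotype association

`anova_map()` colors each unit by $-\log_{10} p$ of a one-way ANOVA of
its weights across phenotype categories (vectorized sums of squares, so a
2500-unit map is one matrix pass); `group_anova_portraits()` renders
one-vs-rest two-group maps per group (e.g. country-wise portraits).
`pointbiserial_map()` is the Pearson correlation of unit weights with a
0/1 indicator. Per unit it equals the group mean difference scaled by one
global constant over the unit's weight standard deviation, so the map is
the *standardized* difference portrait; against the raw difference
portrait the agreement is close but not exact.

Maps are computed on meta-SNP weights; `top_correlated_snps()` goes back
to the raw SNP scores (default top 100), annotates unit and spot, and adds
Benjamini–Hochberg q-values computed over all SNPs. Map p-values carry no
multiple-testing correction: the maps are visual instruments.

## Diversity topology

All accession-level analyses run on the Pearson correlation between
portraits, distance $d = 1 - r$: PCA of the accession × unit matrix,
similarity nets (edge iff $r \ge 0.5$ by default), a deterministic Kruskal
MST (ties in edge weight broken lexicographically), hierarchical trees
(average linkage by default; complete and Ward.D2 available; Newick
export), and silhouette-based cluster stability with redistribution
targets: $s = (b-a)/\max(a,b)$ per accession, the target being the cluster
realizing $b$; members of singleton clusters are scored 0.

To read branches off an MST of noisy panel data (the tree is bushy, so
removing junction nodes over-fragments it), the study analyses cut the
longest edges subject to both sides retaining at least 15 accessions;
four cuts yield the four arms plus the central crossroad.

## Flood pseudotime

`knn_graph()` builds a union-symmetrized kNN graph on $d = 1 - r$.
`flood_pseudotime()` repeats a randomized flood `n_floods = 100` times:
each edge survives with probability `q = 0.8`, and every node records its
BFS hop depth from the root set; pseudotime is the mean depth over the
floods that reached the node, min–max normalized to [0, 1]. Roots are user
input (an accession set or a metadata group); `propose_tips()` suggests
one tip per SNN cluster. `assign_branches()` sends `n_walks = 500` biased
walks per tip downhill (next node among neighbors with PT
$\le$ current + `epsilon` = 0.02, probability $\propto 1/d$); a node joins a
tip's branch when that tip owns $\ge 0.6$ of its visits, otherwise the
shared trunk. LOESS (degree-1, tricube, span 0.5) fits spot profiles
against PT per branch; branches under 5 accessions return raw points only.

The neighborhood size deserves care on block-structured panels: for
clustering, small k (the default 15) keeps neighborhoods population-pure;
for floods, k must *exceed* the size of a homogeneous population block
(the study uses k = 40 against 30-accession populations), otherwise hop
depths saturate inside blocks and the depth signal blurs. Both uses take
the graph as an argument, so the choice is explicit.

`snn_cluster_accessions()` clusters the shared-nearest-neighbor graph
(Jaccard overlap of closed neighborhoods, edges below 1/15 pruned) with
seeded Louvain modularity.

## The synthetic study

`simulate_vinelike()` emulates the structure of a real cultivar panel:
nine populations on a four-branch dissemination cross (root plus four
two-population chains), Balding–Nichols drift $F = 0.08$ per edge
(ancestral frequencies Uniform(0.05, 0.5); child frequencies
Beta-distributed around the parent with variance $F p (1-p)$, clipped to
[0.001, 0.999]), 4000 SNPs, 30 accessions per population under
Hardy–Weinberg, and a table/wine/double utilization gradient across the
branches with optional planted causal SNPs (frequency shift `effect`
between the category-enriched branch groups). Everything is returned with
ground truth (population map, per-population frequencies, causal ids) and
is bit-reproducible under the seed.

What it does *not* emulate — and hence what passing tests do not show
about real panels: linkage disequilibrium and recombination structure,
clonal pedigrees and admixture between branches, genotyping error and
ascertainment bias, and missingness patterns. Drift here is tree-shaped
and homogeneous; real panels mix all of the above.

Test and acceptance runs use these study sizes: the full 4000 × 270
fixture with the 50 × 50 grid and 20 epochs for the twenty-seed recovery
suites; 800 × 90 fixtures on 15 × 15 grids for unit-level checks; a
two-population, 1000-SNP fixture (drift 0.02, 50 causal SNPs at effect
0.4) for phenotype recovery. Segmentation and trajectory parameters in
those runs are the package defaults except where a scaled fixture
warrants the documented adjustment (e.g. `q_high = 0.95` on small grids,
flood k = 40 as above).

## Known limitations

* No LD pruning, phasing, imputation beyond mean-fill, or multiallelic
  support; kinship/mixed-model association is out of scope.
* Spot counts are threshold-dependent by construction; compare landscapes
  under one configuration only.
* The SOM schedule is this package's own (batch, PCA init, linear radius
  decay); it does not claim bit-compatibility with other SOM software.
* Branch extraction from MSTs and trajectory tip selection are heuristics
  that assume a branched (not clinal or reticulate) structure.
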