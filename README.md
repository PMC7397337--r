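# snpsom

Self-organizing-map (SOM) portrayal of genome-wide SNP genotype data.

`snpsom` turns a biallelic SNP genotype matrix (thousands of SNPs across
hundreds of accessions — grapevine cultivar panels are the motivating case)
into per-accession *genome portraits*: two-dimensional landscapes whose
topology exposes population structure, dissemination paths, and
genotype–phenotype associations, without requiring any specialized genetic
training to read.

## The method

1. **eMAF scoring.** Genotypes are coded 0/1/2 (homozygous major /
   heterozygous / homozygous minor). After orienting each SNP so its minor
   allele is coded upward, the mean code equals twice the minor allele
   frequency (MAF), and the centered *SNP-score*

   ```
   score = code − 2·MAF
   ```

   takes the values −2·MAF, 1 − 2·MAF and 2·(1 − MAF) for the three genotype
   classes. Averaged over a SNP set in one accession, the score is the
   *excess minor allele frequency* (eMAF): `⟨score⟩ = 2·(MAF_accession −
   ⟨MAF⟩)`, i.e. how much more (or less) minor-allele-rich that accession is
   than the population.

2. **SOM portrayal.** A batch Kohonen SOM clusters the SNP score profiles
   onto a rectangular grid (default 50 × 50 = 2500 "meta-SNP" units) by
   Euclidean distance, with a Gaussian neighborhood whose radius decays
   linearly across epochs and deterministic PCA-plane initialization.
   Each accession's column of unit weights, arranged on the grid, is its
   portrait: red mountains = SNP modules with excess minor alleles, blue
   valleys = depleted ones.

3. **Spots.** The per-unit maximum over portraits gives a summary landscape;
   units above a high quantile form 8-connected *spots* — modules of
   correlated SNPs that act as fingerprint features. Spot profiles, call
   matrices, entropies, weighted-topological-overlap (WTO) correlation
   networks and co-occurrence (implication) graphs summarize them.

4. **Phenotype maps.** Per-unit one-way ANOVA (−log10 p) and point-biserial
   correlation maps associate categorical phenotypes (e.g. table vs wine
   utilization) with landscape regions; top-correlated SNP tables drill back
   to individual markers.

5. **Diversity topology and pseudotime.** Pearson correlations between
   portraits drive PCA, similarity nets, minimum spanning trees,
   hierarchical trees and silhouette/redistribution stability analysis;
   a flood pseudotime (repeated BFS over randomly thinned kNN graphs)
   orders accessions from a chosen root and biased tip-walks split them
   into branches — a proxy for dissemination order.

A Balding–Nichols simulator (`simulate_vinelike()` and friends) generates
genotype panels with dissemination-tree population structure, drifted SNP
blocks, correlated phenotypes and full ground truth, so every stage is
testable offline.

## Worked example

```r
library(snpsom)

sim <- simulate_vinelike(n_snps = 800, n_per_pop = 10, seed = 42)
oriented <- orient_minor_allele(sim$genotype)
scores <- compute_snp_scores(oriented$genotype, oriented$maf)
model <- train_som(scores, grid_rows = 15, grid_cols = 15, epochs = 10, seed = 42)
model
#> <snp_som> 15 x 15 grid (K = 225), 800 SNPs, 90 accessions, final QE 5.0899

spots <- spot_segmentation(model, q_high = 0.95, min_size = 3)
spots
#> <spot_map> 2 spot(s) on a 15 x 15 grid (q_high = 0.950, min_size = 3)
tidy(spots)
#> # A tibble: 2 × 5
#>   spot   size n_snps centroid_row centroid_col
#>   <chr> <int>  <int>        <dbl>        <dbl>
#> 1 A         4     27         12           14.8
#> 2 B         4     33         14.5          1.5
```

Each spot is a module of correlated SNPs (here 27 and 33 SNPs) sitting in
one corner of the landscape; on this small simulated panel the strongest two
of the four drifted branches stand out (at the full study size, 4000 SNPs ×
270 accessions on a 50 × 50 grid, the arms each claim a spot). `autoplot(spots)` draws the
summary landscape with lettered spots; `portrait(model, "A2_003")` and
`autoplot()` render single-accession portraits; `portrait_correlation()`,
`minimum_spanning_tree()`, `flood_pseudotime()` and `snn_cluster_accessions()`
take the analysis from the landscape to accession-level topology. The
methods vignette (`vignettes/snpsom-methods.Rmd`) documents the model,
parameters and design choices.

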