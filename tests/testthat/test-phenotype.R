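test_that("per-unit ANOVA matches the stats::aov oracle", {
  # 3 categories x 2 accessions, unit values {1,2},{3,4},{5,6}
  W <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  W <- W[rep(1, 16), ]
  m <- model_from_weights(W, 4, 4)
  labels <- setNames(rep(c("g1", "g2", "g3"), each = 2), colnames(W))
  pm <- anova_map(m, labels)
  oracle <- summary(stats::aov(c(1, 2, 3, 4, 5, 6) ~ factor(rep(1:3, each = 2))))[[1]]
  expect_equal(pm[1, 1], -log10(oracle[["Pr(>F)"]][1]), tolerance = 1e-9)
  # the same F value via the internal statistic
  f <- snpsom:::anova_f_rows(W, factor(rep(c("g1", "g2", "g3"), each = 2)))
  expect_equal(f$f[1], oracle[["F value"]][1], tolerance = 1e-12)
})

test_that("vectorized ANOVA agrees with aov across random units", {
  set.seed(12)
  W <- matrix(rnorm(20 * 9), 20, 9)
  labels <- factor(rep(c("x", "y", "z"), each = 3))
  f <- snpsom:::anova_f_rows(W, labels)
  for (i in c(1, 7, 20)) {
    o <- summary(stats::aov(W[i, ] ~ labels))[[1]]
    expect_equal(f$f[i], o[["F value"]][1], tolerance = 1e-10)
    expect_equal(f$p[i], o[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(13)
  W <- matrix(rnorm(25 * 10), 25, 10)
  labels <- factor(rep(c("a", "b"), each = 5))
  f <- snpsom:::anova_f_rows(W, labels)
  tstats <- apply(W, 1, function(x)
    stats::t.test(x[1:5], x[6:10], var.equal = TRUE)$statistic)
  expect_equal(f$f, unname(tstats^2), tolerance = 1e-9)
})

test_that("equal group distributions give a flat ANOVA map", {
  # identical unit values in both groups: F = 0, -log10(p) = 0
  W <- matrix(rep(c(1, 2, 1, 2), each = 9), 9, 4)
  m <- model_from_weights(W, 3, 3)
  labels <- setNames(c("g1", "g1", "g2", "g2"), colnames(W))
  pm <- anova_map(m, labels)
  expect_true(all(pm == 0))
  expect_true(all(pm >= 0))
})

test_that("small categories are excluded and too few categories error", {
  W <- matrix(rnorm(9 * 5), 9, 5)
  m <- model_from_weights(W, 3, 3)
  labels <- setNames(c("g1", "g1", "g2", "g2", "g3"), colnames(W))
  expect_warning(pm <- anova_map(m, labels), "g3")
  labels2 <- setNames(c("g1", "g1", "g1", "g1", "g3"), colnames(W))
  expect_error(suppressWarnings(anova_map(m, labels2)), "2 usable")
})

test_that("point-biserial map matches the direct Pearson computation", {
  W <- matrix(c(1, 2, 3, 4), 1)[rep(1, 9), ]
  m <- model_from_weights(W, 3, 3)
  ind <- setNames(c(0, 0, 1, 1), colnames(W))
  pm <- pointbiserial_map(m, ind)
  expect_equal(pm[1, 1], 0.894427190999916, tolerance = 1e-12)
  expect_true(all(abs(pm) <= 1))
  # indicator equal to a rescaled copy of the unit profile -> r = 1
  W2 <- matrix(c(0, 0, 1, 1) * 3 + 1, 1)[rep(1, 9), ]
  m2 <- model_from_weights(W2, 3, 3)
  pm2 <- pointbiserial_map(m2, ind)
  expect_equal(pm2[2, 2], 1, tolerance = 1e-12)
})

test_that("point-biserial map is the scaled mean-difference portrait", {
  sv <- small_vinelike_model()
  m <- sv$model
  pop <- sv$sim$truth$populations[m$accession_ids]
  ind <- setNames(as.numeric(startsWith(unname(pop), "A")), m$accession_ids)
  pm <- pointbiserial_map(m, ind)
  diff_grid <- unclass(mean_portrait(m, names(ind)[ind == 1])) -
    unclass(mean_portrait(m, names(ind)[ind == 0]))
  # the point-biserial per unit is the mean difference scaled by one global
  # constant over the unit's weight standard deviation; standardizing the
  # difference portrait makes the ranking identical
  sd_units <- apply(m$weights, 1, sd)
  std_diff <- as.vector(t(diff_grid)) / sd_units
  expect_equal(cor(snpsom:::grid_to_unit_vector(unclass(pm)), std_diff,
                   method = "spearman"), 1, tolerance = 1e-12)
  # unscaled difference portrait still agrees closely in rank
  expect_gt(cor(as.vector(unclass(pm)), as.vector(diff_grid),
                method = "spearman"), 0.9)
  # swapping the coding flips the sign only
  pm_swap <- pointbiserial_map(m, 1 - ind)
  expect_equal(unclass(pm_swap), -unclass(pm), tolerance = 1e-12)
})

test_that("top-correlated SNP tables rank, annotate and truncate", {
  sv <- small_vinelike_model()
  s <- sv$scores
  pop <- sv$sim$truth$populations[s$accession_ids]
  ind <- setNames(as.numeric(startsWith(unname(pop), "B")), s$accession_ids)
  sm <- spot_segmentation(sv$model, q_high = 0.9, min_size = 3)
  top <- top_correlated_snps(s, ind, model = sv$model, spotmap = sm, n = 25)
  expect_equal(nrow(top), 25L)
  expect_true(all(diff(abs(top$r)) <= 1e-12))
  expect_true(all(c("snp_id", "chrom", "pos", "r", "q", "unit_row",
                    "unit_col", "spot") %in% names(top)))
  # direct Pearson spot check on the leader
  lead <- top$snp_id[1]
  expect_equal(top$r[1], cor(s$scores[lead, ], ind), tolerance = 1e-12)
  # default table size is 100 SNPs
  expect_equal(formals(top_correlated_snps)$n, 100)
  # n beyond the SNP count truncates with a warning
  expect_warning(all_snps <- top_correlated_snps(s, ind, n = 1e6), "exceeds")
  expect_equal(nrow(all_snps), nrow(s$scores))
})

test_that("planted causal SNPs dominate the top of the table", {
  tr <- dissemination_tree(data.frame(parent = "R", child = "X", f = 0.02))
  sim <- simulate_genotypes(tr, n_snps = 1000, n_per_pop = 50, seed = 61)
  probs <- list(R = c(table = 1, wine = 0), X = c(table = 0, wine = 1))
  out <- simulate_phenotypes(sim, probs, n_causal = 50, effect = 0.4, seed = 61)
  o <- suppressWarnings(orient_minor_allele(out$genotype))
  s <- compute_snp_scores(o$genotype, o$maf)
  ind <- setNames(as.numeric(out$metadata$utilization == "table"),
                  out$metadata$accession_id)
  top <- top_correlated_snps(s, ind, n = 50)
  hit <- mean(top$snp_id %in% out$truth$causal$utilization)
  expect_gte(hit, 0.7)
})

test_that("label permutation suppresses the point-biserial signal", {
  tr <- dissemination_tree(data.frame(parent = "R", child = "X", f = 0.02))
  sim <- simulate_genotypes(tr, n_snps = 400, n_per_pop = 30, seed = 71)
  probs <- list(R = c(table = 1, wine = 0), X = c(table = 0, wine = 1))
  out <- simulate_phenotypes(sim, probs, n_causal = 30, effect = 0.4, seed = 71)
  o <- suppressWarnings(orient_minor_allele(out$genotype))
  s <- compute_snp_scores(o$genotype, o$maf)
  causal <- out$truth$causal$utilization
  ind <- as.numeric(out$metadata$utilization == "table")
  observed <- mean(abs(suppressWarnings(cor(t(s$scores[causal, ]), ind))),
                   na.rm = TRUE)
  set.seed(5)
  perm_means <- replicate(100, {
    mean(abs(suppressWarnings(cor(t(s$scores[causal, ]), sample(ind)))),
         na.rm = TRUE)
  })
  expect_lt((sum(perm_means >= observed) + 1) / 101, 0.05)
})

test_that("group ANOVA portraits localize group-specific drift", {
  set.seed(31)
  W <- matrix(rnorm(64 * 12, mean = 0.05, sd = 0.02), 64, 12)
  # three groups of four accessions; g1 drifts in units 1:8, g2 in 57:64,
  # g3 carries no drift anywhere
  W[1:8, 1:4] <- W[1:8, 1:4] + 1
  W[57:64, 5:8] <- W[57:64, 5:8] + 1
  m <- model_from_weights(W, 8, 8)
  labels <- setNames(rep(c("g1", "g2", "g3"), each = 4), colnames(W))
  maps <- group_anova_portraits(m, labels)
  expect_named(maps, c("g1", "g2", "g3"))
  g1_units <- order(snpsom:::grid_to_unit_vector(maps$g1), decreasing = TRUE)[1:8]
  expect_setequal(g1_units, 1:8)
  g2_units <- order(snpsom:::grid_to_unit_vector(maps$g2), decreasing = TRUE)[1:8]
  expect_setequal(g2_units, 57:64)
  # a group equal to the full set is rejected
  expect_error(
    suppressWarnings(group_anova_portraits(m, setNames(rep("g", 12), colnames(W)))),
    "one-vs-rest")
})

test_that("permuted labels flatten the group ANOVA portraits", {
  sv <- small_vinelike_model()
  m <- sv$model
  pop <- sv$sim$truth$populations[m$accession_ids]
  branch <- substr(unname(pop), 1, 1)
  names(branch) <- m$accession_ids
  maps_true <- group_anova_portraits(m, branch)
  q_true <- quantile(unclass(maps_true[["A"]]), 0.95)
  set.seed(77)
  hits <- 0L
  for (i in 1:5) {
    perm <- setNames(sample(branch), names(branch))
    maps_perm <- group_anova_portraits(m, perm)
    if (quantile(unclass(maps_perm[["A"]]), 0.95) <= q_true) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("one-vs-rest indicators cover each category", {
  x <- setNames(c("table", "wine", "double", "wine"), paste0("a", 1:4))
  inds <- one_vs_rest(x)
  expect_named(inds, c("double", "table", "wine"))
  expect_equal(unname(inds$wine), c(0, 1, 0, 1))
  expect_equal(names(inds$wine), names(x))
})
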