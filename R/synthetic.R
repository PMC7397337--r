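#' Build a dissemination tree of populations
#'
#' Populations are related by a rooted tree whose edges carry a drift
#' coefficient `F` in (0, 1): the larger `F`, the further a child population's
#' allele frequencies drift from its parent's under the Balding-Nichols model.
#'
#' @param edges A data frame with columns `parent`, `child`, `f` (drift per
#'   edge), or `NULL` for a single-population tree.
#' @param root Root label; inferred as the unique parent that is never a child
#'   when omitted.
#' @return A `pop_tree` object: list with `nodes`, `edges` (tibble), `root`,
#'   and `depth` (named integer, generations from the root).
#' @export
dissemination_tree <- function(edges = NULL, root = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    root <- root %||% "P0"
    return(structure(list(nodes = root, edges = tibble::tibble(
      parent = character(), child = character(), f = numeric()),
      root = root, depth = setNames(0L, root)), class = "pop_tree"))
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child", "f") %in% names(edges)))
  if (any(edges$f <= 0 | edges$f >= 1)) {
    rlang::abort("drift coefficient f must lie strictly in (0, 1) on every edge")
  }
  if (anyDuplicated(edges$child)) {
    rlang::abort("a population has multiple parents: not a tree")
  }
  nodes <- union(edges$parent, edges$child)
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1) {
    rlang::abort(sprintf("expected a single root, found %d (%s)",
                         length(roots), paste(roots, collapse = ", ")))
  }
  if (!is.null(root) && root != roots) rlang::abort("stated root does not match the edge list")
  root <- roots
  # depth by walking from the root; a cycle or disconnected node never resolves
  depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier) > 0) {
    kids <- edges$child[edges$parent %in% frontier]
    depth[kids] <- depth[edges$parent[match(kids, edges$child)]] + 1L
    frontier <- kids
  }
  if (anyNA(depth)) {
    rlang::abort("edge list contains a cycle or disconnected populations")
  }
  structure(list(nodes = nodes, edges = edges, root = root, depth = depth),
            class = "pop_tree")
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(sprintf("<pop_tree> %d populations, root '%s', max depth %d\n",
              length(x$nodes), x$root, max(x$depth)))
  invisible(x)
}

#' The default "vinelike" dissemination tree
#'
#' A root population with four chains of two populations each (nine
#' populations, depths 0/1/2): a cross-shaped dissemination scaffold with
#' four drifted branches, mirroring a crop spreading from one origin along
#' four routes.
#'
#' @param f Drift coefficient applied to every edge (default 0.08).
#' @return A `pop_tree`.
#' @export
vinelike_tree <- function(f = 0.08) {
  arms <- c("A", "B", "C", "D")
  edges <- tibble::tibble(
    parent = c(rep("R", 4), paste0(arms, 1)),
    child = c(paste0(arms, 1), paste0(arms, 2)),
    f = f
  )
  dissemination_tree(edges)
}

#' Simulate genotypes under Balding-Nichols drift along a dissemination tree
#'
#' Each SNP draws an ancestral allele frequency `p0 ~ Uniform(0.05, 0.5)`;
#' along every edge with drift `F` the child population's frequency is drawn
#' from `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` (mean `p`, variance
#' `F p (1 - p)`), clipped to `[0.001, 0.999]`. Genotype codes are then
#' binomial draws `Binomial(2, p_pop)` under Hardy-Weinberg equilibrium.
#' Codes count the allele whose ancestral frequency was drawn, so they are
#' dosage codes; pass the result through [orient_minor_allele()] before
#' scoring.
#'
#' @param tree A `pop_tree`.
#' @param n_snps Number of SNPs (default 4000).
#' @param n_per_pop Accessions per population (default 30).
#' @param seed Integer seed; the output is fully determined by it.
#' @return A list with `genotype` (a [snp_geno]) and `truth` (a `truth_table`:
#'   accession -> population map, ancestral and per-population allele
#'   frequencies, empty causal set, seed).
#' @export
simulate_genotypes <- function(tree, n_snps = 4000, n_per_pop = 30, seed = 1) {
  stopifnot(inherits(tree, "pop_tree"))
  if (n_snps < 1 || n_per_pop < 1) rlang::abort("n_snps and n_per_pop must be >= 1")
  set.seed(seed)
  p0 <- runif(n_snps, 0.05, 0.5)
  freqs <- matrix(NA_real_, n_snps, length(tree$nodes),
                  dimnames = list(NULL, tree$nodes))
  freqs[, tree$root] <- p0
  # walk edges in depth order so each parent's frequencies exist first
  ord <- order(tree$depth[tree$edges$child])
  for (i in ord) {
    p <- freqs[, tree$edges$parent[i]]
    f <- tree$edges$f[i]
    child <- rbeta(n_snps, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    freqs[, tree$edges$child[i]] <- pmin(pmax(child, 0.001), 0.999)
  }
  pops <- rep(tree$nodes, each = n_per_pop)
  acc_ids <- paste0(pops, "_", sprintf("%03d", sequence(rep(n_per_pop, length(tree$nodes)))))
  codes <- matrix(NA_integer_, n_snps, length(acc_ids))
  for (j in seq_along(acc_ids)) {
    codes[, j] <- rbinom(n_snps, 2, freqs[, pops[j]])
  }
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  # synthetic coordinates: SNPs spread uniformly over 19 chromosome labels
  chrom <- as.character(rep_len(1:19, n_snps))
  pos <- as.integer(10000L * ((seq_len(n_snps) - 1L) %/% 19L + 1L))
  g <- snp_geno(codes, snp_ids, chrom, pos, acc_ids)
  truth <- structure(list(
    populations = setNames(pops, acc_ids),
    ancestral_freq = setNames(p0, snp_ids),
    pop_freq = `dimnames<-`(freqs, list(snp_ids, tree$nodes)),
    causal = list(),
    tree = tree,
    seed = seed
  ), class = "truth_table")
  list(genotype = g, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d accessions in %d populations, %d SNPs, seed %d\n",
              length(x$populations), ncol(x$pop_freq), nrow(x$pop_freq), x$seed))
  invisible(x)
}

#' Simulate categorical phenotypes correlated with population structure
#'
#' Draws one utilization category per accession from its population's
#' category distribution. Optionally plants `n_causal` causal SNPs: for those
#' SNPs the allele frequency is shifted by `+effect/2` in populations whose
#' most probable category is the first category and by `-effect/2` in the
#' remaining populations, and genotypes are re-drawn; causal SNP ids are
#' recorded in the truth table.
#'
#' @param sim A list with `genotype` and `truth` as from [simulate_genotypes()].
#' @param assignment Named list or matrix: per population, a named probability
#'   vector over categories (each summing to one).
#' @param n_causal Number of causal SNPs to plant (default 0).
#' @param effect Allele-frequency shift between the category-enriched
#'   population groups (default 0.4).
#' @param seed Integer seed.
#' @return A list with `genotype` (possibly modified), `truth` (causal ids
#'   recorded), and `metadata` (tibble: accession_id, population, region,
#'   utilization).
#' @export
simulate_phenotypes <- function(sim, assignment, n_causal = 0, effect = 0.4, seed = 1) {
  g <- sim$genotype
  truth <- sim$truth
  pops <- truth$populations
  if (is.matrix(assignment)) {
    assignment <- setNames(
      lapply(seq_len(nrow(assignment)), function(i) assignment[i, ]),
      rownames(assignment))
  }
  missing_pops <- setdiff(unique(pops), names(assignment))
  if (length(missing_pops) > 0) {
    rlang::abort(paste0("no category distribution for population(s): ",
                        paste(missing_pops, collapse = ", ")))
  }
  for (p in names(assignment)) {
    if (abs(sum(assignment[[p]]) - 1) > 1e-8) {
      rlang::abort(sprintf("category probabilities for population '%s' do not sum to 1", p))
    }
  }
  set.seed(seed)
  categories <- names(assignment[[1]])
  util <- vapply(pops, function(p) {
    sample(names(assignment[[p]]), 1, prob = assignment[[p]])
  }, character(1))
  causal_ids <- character(0)
  if (n_causal > 0) {
    first_cat <- categories[1]
    enriched <- names(assignment)[vapply(assignment, function(pr) {
      names(pr)[which.max(pr)] == first_cat
    }, logical(1))]
    causal_ids <- sample(g$snp_ids, n_causal)
    idx <- match(causal_ids, g$snp_ids)
    for (pop in colnames(truth$pop_freq)) {
      shift <- if (pop %in% enriched) effect / 2 else -effect / 2
      pnew <- pmin(pmax(truth$pop_freq[idx, pop] + shift, 0.001), 0.999)
      truth$pop_freq[idx, pop] <- pnew
      cols <- which(pops == pop)
      for (j in cols) {
        g$codes[idx, j] <- rbinom(length(idx), 2, pnew)
      }
    }
  }
  truth$causal <- list(utilization = causal_ids)
  md <- tibble::tibble(
    accession_id = names(pops),
    population = unname(pops),
    region = unname(pops),
    utilization = unname(util)
  )
  list(genotype = g, truth = truth, metadata = md)
}

#' Generate the default "vinelike" study fixture
#'
#' Nine populations on the four-branch cross ([vinelike_tree()]), drift
#' `F = 0.08` per edge, 4000 SNPs, 30 accessions per population, and a
#' utilization gradient: branch-A/B populations favour `table`, branch-C/D
#' populations favour `wine`, the root is mixed.
#'
#' @param n_snps,n_per_pop,f Override the fixture dimensions.
#' @param n_causal,effect Causal SNPs planted for the utilization contrast.
#' @param seed Integer seed.
#' @return A list with `genotype`, `truth`, `metadata`.
#' @export
simulate_vinelike <- function(n_snps = 4000, n_per_pop = 30, f = 0.08,
                              n_causal = 0, effect = 0.4, seed = 1) {
  tree <- vinelike_tree(f)
  sim <- simulate_genotypes(tree, n_snps = n_snps, n_per_pop = n_per_pop, seed = seed)
  probs <- list(
    R = c(table = 0.4, wine = 0.4, double = 0.2),
    A1 = c(table = 0.7, wine = 0.2, double = 0.1),
    A2 = c(table = 0.8, wine = 0.1, double = 0.1),
    B1 = c(table = 0.7, wine = 0.2, double = 0.1),
    B2 = c(table = 0.8, wine = 0.1, double = 0.1),
    C1 = c(table = 0.2, wine = 0.7, double = 0.1),
    C2 = c(table = 0.1, wine = 0.8, double = 0.1),
    D1 = c(table = 0.2, wine = 0.7, double = 0.1),
    D2 = c(table = 0.1, wine = 0.8, double = 0.1)
  )
  simulate_phenotypes(sim, probs, n_causal = n_causal, effect = effect,
                      seed = seed + 1000L)
}

#' Write a simulated fixture to disk
#'
#' Writes the genotype TSV and metadata TSV in the formats the loaders read,
#' plus the truth table as JSON.
#'
#' @param sim A list with `genotype`, `truth`, and optionally `metadata`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_table(sim$genotype, file.path(dir, "genotypes.tsv"))
  if (!is.null(sim$metadata)) {
    readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  }
  truth <- sim$truth
  jsonlite::write_json(list(
    populations = as.list(truth$populations),
    ancestral_freq = as.list(truth$ancestral_freq),
    pop_freq = as.data.frame(truth$pop_freq),
    causal = truth$causal,
    seed = truth$seed
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
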