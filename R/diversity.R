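#' Pearson correlation between accession portraits
#'
#' @param model A `snp_som` object (columns of the weight matrix are the
#'   portraits), or a numeric units x accessions matrix.
#' @return Symmetric accession x accession correlation matrix with unit
#'   diagonal; accessions with constant portraits get `NA` rows/columns.
#' @export
portrait_correlation <- function(model) {
  W <- if (inherits(model, "snp_som")) model$weights else as.matrix(model)
  if (ncol(W) < 2) rlang::abort("need at least 2 accessions")
  sds <- apply(W, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    rlang::warn(paste0("constant portrait(s), correlations reported as missing: ",
                       paste(colnames(W)[constant], collapse = ", ")))
  }
  r <- suppressWarnings(cor(W))
  r[constant, ] <- NA
  r[, constant] <- NA
  diag(r) <- 1
  r
}

#' Principal components of the accession x meta-SNP matrix
#'
#' PCA of the accessions over the unit weights (centered per unit).
#'
#' @param model A `snp_som` object.
#' @param n_components Number of components to return (default 3).
#' @return List with `coords` (tibble: `accession_id`, `PC1`, ...) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_accessions <- function(model, n_components = 3) {
  stopifnot(inherits(model, "snp_som"))
  if (n_components <= 0) rlang::abort("n_components must be positive")
  X <- t(model$weights)
  n_components <- min(n_components, ncol(X), nrow(X))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  coords <- tibble::as_tibble(p$x[, seq_len(n_components), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(accession_id = rownames(X)), coords)
  list(coords = coords, explained_variance = ev[seq_len(n_components)])
}

#' Correlation similarity net between accessions
#'
#' Connects accessions whose portrait correlation is at least `threshold`;
#' isolated accessions are retained as nodes.
#'
#' @param corr Accession correlation matrix from [portrait_correlation()].
#' @param threshold Correlation threshold in (-1, 1) (default 0.5).
#' @return An [igraph::igraph] with edge attributes `r` and `distance`
#'   (`1 - r`) and graph attribute `kind = "net"`.
#' @export
similarity_net <- function(corr, threshold = 0.5) {
  if (threshold <= -1 || threshold >= 1) rlang::abort("threshold must lie in (-1, 1)")
  adj <- corr >= threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(gr)
  if (nrow(ends) > 0) {
    r <- corr[cbind(match(ends[, 1], rownames(corr)), match(ends[, 2], rownames(corr)))]
    igraph::E(gr)$r <- r
    igraph::E(gr)$distance <- 1 - r
  }
  gr$kind <- "net"
  gr
}

#' Minimum spanning tree of accessions on correlation distance
#'
#' Kruskal's algorithm on the distance `d = 1 - r`; equal-weight edges are
#' taken in lexicographic node-pair order, so the tree is deterministic.
#'
#' @param corr Accession correlation matrix (no missing values).
#' @return An [igraph::igraph] with `n - 1` edges, edge attributes `r` and
#'   `distance`, graph attribute `kind = "mst"`.
#' @export
minimum_spanning_tree <- function(corr) {
  n <- nrow(corr)
  if (n < 2) rlang::abort("need at least 2 accessions")
  if (anyNA(corr)) rlang::abort("correlation matrix contains missing values")
  ids <- rownames(corr) %||% as.character(seq_len(n))
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  d <- 1 - corr[pairs]
  ord <- order(d, ids[pairs[, 1]], ids[pairs[, 2]])
  # union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  take <- logical(length(ord))
  n_edges <- 0L
  for (e in ord) {
    a <- find(pairs[e, 1])
    b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      take[e] <- TRUE
      n_edges <- n_edges + 1L
      if (n_edges == n - 1L) break
    }
  }
  el <- pairs[take, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
               distance = 1 - corr[el], r = corr[el]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  gr$kind <- "mst"
  gr
}

#' Hierarchical clustering tree of accessions
#'
#' Agglomerative clustering on the correlation distance `d = 1 - r`.
#'
#' @param corr Accession correlation matrix.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`
#'   (Ward.D2 on the distance).
#' @return An `hclust` object.
#' @export
hierarchical_tree <- function(corr, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  d <- as.dist(1 - corr)
  hclust(d, method = method)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cluster stability (silhouette) and redistribution analysis
#'
#' Per accession, with distances `d = 1 - r`: `a` = mean distance to its own
#' cluster's other members, `b` = the smallest mean distance to another
#' cluster, and the silhouette score `s = (b - a) / max(a, b)`. Accessions
#' with negative scores better match another cluster; their redistribution
#' target is the cluster realizing `b`. Members of singleton clusters score 0
#' (with a warning).
#'
#' @param corr Accession correlation matrix.
#' @param labels Cluster label per accession (named or in matrix order).
#' @return Tibble with `accession_id`, `cluster`, `a`, `b`, `silhouette`,
#'   `target` (the nearest other cluster; equals `cluster`'s best alternative
#'   regardless of sign).
#' @export
cluster_stability <- function(corr, labels) {
  ids <- rownames(corr)
  labels <- align_labels(labels, ids)
  if (length(unique(labels)) < 2) rlang::abort("need at least 2 clusters")
  d <- 1 - corr
  singleton <- names(which(table(labels) == 1))
  if (length(singleton) > 0) {
    rlang::warn(paste0("singleton cluster(s), member scores set to 0: ",
                       paste(singleton, collapse = ", ")))
  }
  purrr::map_dfr(seq_along(ids), function(i) {
    own <- labels[i]
    own_members <- which(labels == own)
    others <- setdiff(unique(labels), own)
    bvals <- vapply(others, function(cl) mean(d[i, labels == cl]), numeric(1))
    b <- min(bvals)
    target <- others[which.min(bvals)]
    if (length(own_members) == 1) {
      a <- NA_real_
      s <- 0
    } else {
      a <- mean(d[i, setdiff(own_members, i)])
      s <- (b - a) / max(a, b)
    }
    tibble::tibble(accession_id = ids[i], cluster = own, a = a, b = b,
                   silhouette = s, target = target)
  })
}
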