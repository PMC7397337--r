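#' Symmetrized k-nearest-neighbour graph of accessions
#'
#' Builds a kNN graph on the correlation distance `d = 1 - r` between
#' portraits and symmetrizes it by edge union, so every node keeps degree of
#' at least `k`.
#'
#' @param model A `snp_som` object or a precomputed accession correlation
#'   matrix.
#' @param k Number of neighbours (default 15; must be `< n`).
#' @return An [igraph::igraph] with edge attribute `distance` and graph
#'   attribute `kind = "knn"`; a warning lists components when the graph is
#'   disconnected.
#' @export
knn_graph <- function(model, k = 15) {
  corr <- if (inherits(model, "snp_som")) portrait_correlation(model) else model
  n <- nrow(corr)
  if (k >= n) rlang::abort("k must be smaller than the number of accessions")
  d <- 1 - corr
  diag(d) <- Inf
  ids <- rownames(d) %||% as.character(seq_len(n))
  edges <- purrr::map_dfr(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    tibble::tibble(from = ids[i], to = ids[nb], distance = d[i, nb])
  })
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(key), ]
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)
  if (comp$no > 1) {
    rlang::warn(sprintf("kNN graph is disconnected (%d components of sizes %s)",
                        comp$no, paste(comp$csize, collapse = ", ")))
  }
  gr$kind <- "knn"
  gr
}

#' Flood pseudotime from a root set
#'
#' Repeats a randomized breadth-first "flood": per iteration every edge is
#' independently retained with probability `q`, and each node records its
#' hop depth from the root set on the thinned graph. Pseudotime is the mean
#' depth over the iterations in which the node was reached, min-max
#' normalized to `[0, 1]` (roots at 0). With `q = 1` this is the
#' deterministic BFS depth.
#'
#' @param graph An accession graph from [knn_graph()].
#' @param root_ids Non-empty character vector of root accessions.
#' @param n_floods Number of flood iterations (default 100).
#' @param q Per-edge retention probability in (0, 1] (default 0.8).
#' @param seed Integer seed.
#' @return Named numeric vector of pseudotime in `[0, 1]`; nodes never
#'   reached are `NA` (with a warning).
#' @export
flood_pseudotime <- function(graph, root_ids, n_floods = 100, q = 0.8, seed = 1) {
  ids <- igraph::V(graph)$name
  if (length(root_ids) == 0) rlang::abort("root set is empty")
  if (!all(root_ids %in% ids)) rlang::abort("unknown root accession(s)")
  if (q <= 0 || q > 1) rlang::abort("q must lie in (0, 1]")
  set.seed(seed)
  ne <- igraph::ecount(graph)
  depth_sum <- setNames(numeric(length(ids)), ids)
  reach_cnt <- setNames(numeric(length(ids)), ids)
  for (it in seq_len(n_floods)) {
    g_it <- if (q < 1) igraph::subgraph_from_edges(
      graph, which(runif(ne) <= q), delete.vertices = FALSE) else graph
    dd <- igraph::distances(g_it, v = root_ids, weights = NA)
    depth <- apply(dd, 2, min)
    reached <- is.finite(depth)
    depth_sum[reached] <- depth_sum[reached] + depth[reached]
    reach_cnt <- reach_cnt + reached
  }
  pt <- ifelse(reach_cnt > 0, depth_sum / reach_cnt, NA_real_)
  if (anyNA(pt)) {
    rlang::warn(sprintf("%d node(s) never reached from the root set", sum(is.na(pt))))
  }
  rng <- range(pt, na.rm = TRUE)
  if (diff(rng) > 0) {
    pt <- (pt - rng[1]) / (rng[2] - rng[1])
  } else {
    pt[!is.na(pt)] <- 0
  }
  pt
}

#' Assign branched trajectory segments by biased tip walks
#'
#' From each tip, `n_walks` random walks step to neighbours with pseudotime
#' at most `current + epsilon` (probability proportional to `1/distance`),
#' descending towards the root. Per-node visitation shares per tip decide the
#' assignment: a node joins a tip's branch when that tip accounts for at
#' least `trunk_threshold` of its visits, otherwise it joins the shared
#' trunk. The branch tree links every tip segment to the trunk, which is
#' rooted at the root set.
#'
#' @param graph Accession graph with `distance` edge attribute.
#' @param pt Named pseudotime vector from [flood_pseudotime()].
#' @param tips Named list of tip accession-id vectors (one entry per tip).
#' @param root_ids Root accessions (pseudotime origin).
#' @param n_walks Walks per tip (default 500).
#' @param epsilon Pseudotime slack per step (default 0.02).
#' @param trunk_threshold Visit share needed to claim a node (default 0.6).
#' @param max_steps Hard cap on walk length (default `2 * n` nodes).
#' @param seed Integer seed.
#' @return A `snp_trajectory`: tibble `assignments` (`accession_id`, `pt`,
#'   `branch`), `tree` (segment tibble with parents), visit matrix, and
#'   parameters.
#' @export
assign_branches <- function(graph, pt, tips, root_ids = NULL, n_walks = 500,
                            epsilon = 0.02, trunk_threshold = 0.6,
                            max_steps = NULL, seed = 1) {
  ids <- igraph::V(graph)$name
  if (length(tips) == 0) rlang::abort("need at least one tip set")
  if (is.null(names(tips))) names(tips) <- paste0("branch", seq_along(tips))
  if (anyNA(pt[unlist(tips)])) rlang::abort("all tip accessions must have defined pseudotime")
  set.seed(seed)
  max_steps <- max_steps %||% (2L * length(ids))
  adj <- igraph::as_adj_list(graph)
  # per-node neighbour ids and distances, looked up once
  nb_ids <- lapply(adj, function(v) ids[as.integer(v)])
  el <- igraph::as_edgelist(graph)
  ew <- igraph::E(graph)$distance %||% rep(1, nrow(el))
  dist_lookup <- new.env(hash = TRUE)
  for (i in seq_len(nrow(el))) {
    assign(paste(el[i, 1], el[i, 2]), ew[i], envir = dist_lookup)
    assign(paste(el[i, 2], el[i, 1]), ew[i], envir = dist_lookup)
  }
  nb_dist <- lapply(seq_along(ids), function(i) {
    vapply(nb_ids[[i]], function(j) get(paste(ids[i], j), envir = dist_lookup),
           numeric(1))
  })
  names(nb_ids) <- ids
  names(nb_dist) <- ids
  visits <- matrix(0, length(ids), length(tips), dimnames = list(ids, names(tips)))
  trapped <- 0L
  root_ids <- root_ids %||% names(pt)[!is.na(pt) & pt == 0]
  for (t in seq_along(tips)) {
    tipset <- tips[[t]]
    for (w in seq_len(n_walks)) {
      cur <- if (length(tipset) == 1) tipset else sample(tipset, 1)
      seen <- character(0)
      for (step in seq_len(max_steps)) {
        seen <- c(seen, cur)
        if (cur %in% root_ids) break
        nbs <- nb_ids[[cur]]
        ok <- !is.na(pt[nbs]) & pt[nbs] <= pt[cur] + epsilon & !(nbs %in% seen)
        if (!any(ok)) {
          trapped <- trapped + 1L
          break
        }
        cand <- nbs[ok]
        wts <- 1 / pmax(nb_dist[[cur]][ok], 1e-12)
        cur <- if (length(cand) == 1) cand else sample(cand, 1, prob = wts)
      }
      uniq <- unique(seen)
      visits[uniq, t] <- visits[uniq, t] + 1
    }
  }
  total <- rowSums(visits)
  share <- visits / pmax(total, 1)
  branch <- rep(NA_character_, length(ids))
  names(branch) <- ids
  visited <- total > 0
  branch[visited] <- "trunk"
  for (t in seq_along(tips)) {
    claim <- visited & share[, t] >= trunk_threshold
    branch[claim] <- names(tips)[t]
  }
  tree <- tibble::tibble(
    segment = c("trunk", names(tips)),
    parent = c(NA_character_, rep("trunk", length(tips))),
    n_accessions = c(sum(branch == "trunk", na.rm = TRUE),
                     vapply(names(tips), function(t) sum(branch == t, na.rm = TRUE),
                            numeric(1)))
  )
  structure(list(
    assignments = tibble::tibble(accession_id = ids, pt = unname(pt[ids]),
                                 branch = unname(branch)),
    tree = tree, visits = visits, trapped_walks = trapped,
    root_ids = root_ids, tips = tips,
    params = list(n_walks = n_walks, epsilon = epsilon,
                  trunk_threshold = trunk_threshold, seed = seed)
  ), class = "snp_trajectory")
}

#' @export
print.snp_trajectory <- function(x, ...) {
  cat(sprintf("<snp_trajectory> %d accessions, %d branch(es) + trunk\n",
              nrow(x$assignments), length(x$tips)))
  invisible(x)
}

#' Tidy a trajectory
#'
#' @param x A `snp_trajectory`.
#' @param ... Unused.
#' @return The assignment tibble (`accession_id`, `pt`, `branch`).
#' @export
tidy.snp_trajectory <- function(x, ...) x$assignments

#' Summarize a trajectory
#'
#' @param x A `snp_trajectory`.
#' @param ... Unused.
#' @return One-row tibble with branch count, trunk size, PT range, and
#'   trapped-walk count.
#' @export
glance.snp_trajectory <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x$assignments),
    n_branches = length(x$tips),
    trunk_size = sum(x$assignments$branch == "trunk", na.rm = TRUE),
    unassigned = sum(is.na(x$assignments$branch)),
    pt_min = min(x$assignments$pt, na.rm = TRUE),
    pt_max = max(x$assignments$pt, na.rm = TRUE),
    trapped_walks = x$trapped_walks
  )
}

#' Propose tips from graph clusters
#'
#' Helper proposing one tip per community: the highest-pseudotime accession
#' of each shared-nearest-neighbour cluster that does not contain a root.
#'
#' @param graph Accession graph.
#' @param pt Pseudotime vector.
#' @param k Neighbourhood size for the SNN clustering.
#' @param seed Integer seed.
#' @return Named list of single-accession tip sets.
#' @export
propose_tips <- function(graph, pt, k = 15, seed = 1) {
  cl <- snn_cluster_accessions(graph, seed = seed)
  roots <- names(pt)[!is.na(pt) & pt == 0]
  out <- list()
  for (g in sort(unique(cl))) {
    members <- names(cl)[cl == g]
    if (any(members %in% roots)) next
    m_pt <- pt[members]
    if (all(is.na(m_pt))) next
    out[[paste0("tip", g)]] <- members[which.max(m_pt)]
  }
  out
}

#' LOESS pseudotime profiles of spot scores
#'
#' Per branch (trunk included) and spot, fits a locally weighted linear
#' regression (tricube weights) of the spot eMAF profile against pseudotime.
#' Branches with fewer than 5 accessions return raw points without a fit.
#'
#' @param trajectory A `snp_trajectory`.
#' @param profiles A `spot_profiles` object.
#' @param span LOESS span in (0, 1] (default 0.5).
#' @return Tibble with `spot`, `branch`, `accession_id`, `pt`, `emaf`,
#'   `fitted` (`NA` when the branch is too small for a fit).
#' @export
pt_profiles <- function(trajectory, profiles, span = 0.5) {
  stopifnot(inherits(trajectory, "snp_trajectory"),
            inherits(profiles, "spot_profiles"))
  if (span <= 0 || span > 1) rlang::abort("span must lie in (0, 1]")
  asn <- trajectory$assignments
  asn <- asn[!is.na(asn$branch) & !is.na(asn$pt), ]
  purrr::map_dfr(rownames(profiles$profiles), function(sp) {
    purrr::map_dfr(unique(asn$branch), function(br) {
      sub <- asn[asn$branch == br, ]
      y <- profiles$profiles[sp, sub$accession_id]
      out <- tibble::tibble(spot = sp, branch = br,
                            accession_id = sub$accession_id,
                            pt = sub$pt, emaf = unname(y),
                            fitted = NA_real_)
      if (nrow(sub) >= 5 && length(unique(sub$pt)) >= 4) {
        fit <- tryCatch(
          loess(emaf ~ pt, data = out, span = span, degree = 1,
                family = "gaussian",
                control = stats::loess.control(surface = "direct")),
          error = function(e) NULL)
        if (!is.null(fit)) out$fitted <- predict(fit, out$pt)
      }
      out
    })
  })
}

#' Branch composition along pseudotime
#'
#' Fraction of each metadata group per pseudotime decile and branch, and
#' overall group fractions per branch.
#'
#' @param trajectory A `snp_trajectory`.
#' @param groups Named group label per accession (e.g., region or
#'   utilization), or a data frame with `accession_id` and `group_col`.
#' @param group_col Column name when `groups` is a data frame.
#' @return List with `by_decile` and `by_branch` tibbles.
#' @export
pt_composition <- function(trajectory, groups, group_col = "utilization") {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[group_col]]), groups$accession_id)
  }
  asn <- trajectory$assignments
  asn <- asn[!is.na(asn$branch) & !is.na(asn$pt), ]
  asn$group <- unname(groups[asn$accession_id])
  asn$decile <- pmin(floor(asn$pt * 10) + 1, 10)
  by_decile <- asn |>
    dplyr::count(.data$branch, .data$decile, .data$group) |>
    dplyr::group_by(.data$branch, .data$decile) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  by_branch <- asn |>
    dplyr::count(.data$branch, .data$group) |>
    dplyr::group_by(.data$branch) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(by_decile = by_decile, by_branch = by_branch)
}

#' Shared-nearest-neighbour clustering of accessions
#'
#' Builds an SNN graph (Jaccard overlap of neighbourhoods, each node's
#' neighbourhood including itself) from the accession graph's adjacency and
#' applies Louvain modularity community detection.
#'
#' @param graph Accession graph from [knn_graph()].
#' @param min_jaccard Drop SNN edges below this overlap (default 1/15).
#' @param seed Integer seed (Louvain is seeded for determinism).
#' @return Named integer vector of cluster labels.
#' @export
snn_cluster_accessions <- function(graph, min_jaccard = 1 / 15, seed = 1) {
  ids <- igraph::V(graph)$name
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  diag(adj) <- TRUE
  j <- jaccard_columns(adj)
  j[j < min_jaccard] <- 0
  diag(j) <- 0
  snn <- igraph::graph_from_adjacency_matrix(j, mode = "undirected",
                                             weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(snn, weights = igraph::E(snn)$weight)
  setNames(igraph::membership(cl), ids)
}
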