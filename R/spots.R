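#' Segment the summary eMAF landscape into spots
#'
#' Builds a summary grid (per-unit maximum over the selected accession
#' portraits by default), marks units above the `q_high` quantile of the
#' summary values, and keeps 8-connected components with at least `min_size`
#' units as spots. Spots are labelled with capital letters in row-major
#' centroid order; a spot's member SNPs are the SNPs assigned to its member
#' units. Only positive ("red") regions are segmented; blue valleys are
#' background.
#'
#' @param model A `snp_som` object.
#' @param accession_ids Accessions whose portraits enter the summary
#'   (default: all).
#' @param q_high Quantile threshold in (0, 1) (default 0.98).
#' @param min_size Minimum spot size in units (default 4).
#' @param summary_stat `"max"` (default, the over-expression summary),
#'   `"mean"`, or `"quantile90"` of portrait values per unit.
#' @return A `spot_map`: list with `label_grid` (integer matrix, 0 =
#'   background), `spots` (tibble: `spot`, `size`, `n_snps`, `centroid_row`,
#'   `centroid_col`, plus list-columns `units` and `snp_ids`), the `summary`
#'   grid, and the thresholds used.
#' @export
spot_segmentation <- function(model, accession_ids = NULL, q_high = 0.98,
                              min_size = 4, summary_stat = c("max", "mean", "quantile90")) {
  stopifnot(inherits(model, "snp_som"))
  summary_stat <- match.arg(summary_stat)
  if (q_high <= 0 || q_high >= 1) rlang::abort("q_high must lie in (0, 1)")
  accession_ids <- accession_ids %||% model$accession_ids
  W <- model$weights[, accession_ids, drop = FALSE]
  summary_units <- switch(summary_stat,
    max = apply(W, 1, max),
    mean = rowMeans(W),
    quantile90 = apply(W, 1, quantile, probs = 0.9, names = FALSE)
  )
  sg <- unit_vector_to_grid(summary_units, model$grid_rows, model$grid_cols)
  thr <- quantile(summary_units, q_high, names = FALSE)
  mask <- sg > thr & sg > 0
  lab <- connected_components8(mask)
  comp_sizes <- tabulate(lab[lab > 0])
  keep <- which(comp_sizes >= min_size)
  uc <- unit_coords(model$grid_rows, model$grid_cols)
  spots <- purrr::map(keep, function(cid) {
    cells <- which(lab == cid, arr.ind = TRUE)
    units <- (cells[, 1] - 1L) * model$grid_cols + cells[, 2]
    list(units = sort(units),
         centroid_row = mean(cells[, 1]), centroid_col = mean(cells[, 2]))
  })
  # order by centroid position, row-major
  ord <- order(vapply(spots, `[[`, numeric(1), "centroid_row"),
               vapply(spots, `[[`, numeric(1), "centroid_col"))
  spots <- spots[ord]
  letters_out <- spot_letters(length(spots))
  label_grid <- matrix(0L, model$grid_rows, model$grid_cols)
  spot_tbl <- purrr::imap_dfr(spots, function(sp, i) {
    cells <- uc[uc$unit %in% sp$units, ]
    for (r in seq_len(nrow(cells))) label_grid[cells$row[r], cells$col[r]] <<- i
    snps <- names(model$assignment)[model$assignment %in% sp$units]
    tibble::tibble(
      spot = letters_out[i], size = length(sp$units), n_snps = length(snps),
      centroid_row = sp$centroid_row, centroid_col = sp$centroid_col,
      units = list(sp$units), snp_ids = list(snps)
    )
  })
  if (length(spots) == 0) {
    spot_tbl <- tibble::tibble(spot = character(), size = integer(),
                               n_snps = integer(), centroid_row = numeric(),
                               centroid_col = numeric(), units = list(),
                               snp_ids = list())
  }
  structure(list(
    label_grid = label_grid, spots = spot_tbl, summary = sg,
    thresholds = list(q_high = q_high, min_size = min_size,
                      summary_stat = summary_stat, cutoff = thr)
  ), class = "spot_map")
}

#' @export
print.spot_map <- function(x, ...) {
  cat(sprintf("<spot_map> %d spot(s) on a %d x %d grid (q_high = %.3f, min_size = %d)\n",
              nrow(x$spots), nrow(x$label_grid), ncol(x$label_grid),
              x$thresholds$q_high, x$thresholds$min_size))
  invisible(x)
}

#' Tidy spot membership
#'
#' @param x A `spot_map`.
#' @param ... Unused.
#' @return Tibble with one row per spot: `spot`, `size`, `n_snps`,
#'   `centroid_row`, `centroid_col`.
#' @export
tidy.spot_map <- function(x, ...) {
  dplyr::select(x$spots, "spot", "size", "n_snps", "centroid_row", "centroid_col")
}

#' Per-unit variance map of the portraits
#'
#' Variance of the unit weight across accessions: spot regions collect the
#' SNPs of largest eMAF variance among accessions.
#'
#' @param model A `snp_som` object.
#' @param accession_ids Accessions to include (default all; at least 2).
#' @return Numeric `grid_rows x grid_cols` matrix.
#' @export
variance_map <- function(model, accession_ids = NULL) {
  stopifnot(inherits(model, "snp_som"))
  accession_ids <- accession_ids %||% model$accession_ids
  if (length(accession_ids) < 2) rlang::abort("variance map needs at least 2 portraits")
  W <- model$weights[, accession_ids, drop = FALSE]
  v <- apply(W, 1, var)
  unit_vector_to_grid(v, model$grid_rows, model$grid_cols)
}

#' Spot profiles, expression calls and per-accession spot statistics
#'
#' The spot profile is the mean eMAF over a spot's member units, per
#' accession. An accession "calls" a spot when the profile value exceeds the
#' accession's own `call_quantile` portrait quantile (default 0.98). The
#' per-accession statistics are the spot count (calls), the Shannon entropy
#' (base 2) of the non-negative renormalized spot profile, and the mean and
#' variance of the spot profile values.
#'
#' @param spotmap A `spot_map`.
#' @param model The `snp_som` the spot map was derived from.
#' @param call_quantile Per-accession portrait quantile used as call
#'   threshold (default 0.98).
#' @return A `spot_profiles` object: `profiles` and `calls` matrices
#'   (spots x accessions) and `accession_stats` tibble.
#' @export
spot_profiles <- function(spotmap, model, call_quantile = 0.98) {
  stopifnot(inherits(spotmap, "spot_map"), inherits(model, "snp_som"))
  if (nrow(spotmap$label_grid) != model$grid_rows ||
      ncol(spotmap$label_grid) != model$grid_cols) {
    rlang::abort("spot map grid does not match the model grid")
  }
  spots <- spotmap$spots
  W <- model$weights
  prof <- matrix(0, nrow(spots), ncol(W),
                 dimnames = list(spots$spot, colnames(W)))
  for (i in seq_len(nrow(spots))) {
    prof[i, ] <- colMeans(W[spots$units[[i]], , drop = FALSE])
  }
  thr <- apply(W, 2, quantile, probs = call_quantile, names = FALSE)
  calls <- sweep(prof, 2, thr, ">")
  stats <- tibble::tibble(
    accession_id = colnames(W),
    spot_count = as.integer(colSums(calls)),
    entropy = apply(prof, 2, profile_entropy),
    mean_emaf = colMeans(prof),
    var_emaf = apply(prof, 2, var)
  )
  if (nrow(spots) == 0) {
    stats$entropy <- 0
    stats$mean_emaf <- 0
    stats$var_emaf <- 0
  }
  structure(list(profiles = prof, calls = calls, accession_stats = stats,
                 call_quantile = call_quantile),
            class = "spot_profiles")
}

#' @export
print.spot_profiles <- function(x, ...) {
  cat(sprintf("<spot_profiles> %d spot(s) x %d accessions\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Tidy spot profiles into long form
#'
#' @param x A `spot_profiles` object.
#' @param ... Unused.
#' @return Tibble with `spot`, `accession_id`, `emaf`, `called`.
#' @export
tidy.spot_profiles <- function(x, ...) {
  tibble::tibble(
    spot = rep(rownames(x$profiles), times = ncol(x$profiles)),
    accession_id = rep(colnames(x$profiles), each = nrow(x$profiles)),
    emaf = as.vector(x$profiles),
    called = as.vector(x$calls)
  )
}

#' Per-group spot call frequencies
#'
#' Fraction of each group's accessions that call each spot (the bar plots of
#' region-wise spot usage).
#'
#' @param profiles A `spot_profiles` object.
#' @param groups Named vector (accession -> group label) or a data frame with
#'   `accession_id` and a group column.
#' @param group_col Column name when `groups` is a data frame.
#' @return Tibble with `group`, `spot`, `frequency`, `n`.
#' @export
spot_frequencies <- function(profiles, groups, group_col = "region") {
  stopifnot(inherits(profiles, "spot_profiles"))
  if (is.data.frame(groups)) {
    groups <- setNames(groups[[group_col]], groups$accession_id)
  }
  acc <- colnames(profiles$calls)
  g <- groups[acc]
  purrr::map_dfr(split(acc, g), function(members) {
    sub <- profiles$calls[, members, drop = FALSE]
    tibble::tibble(spot = rownames(sub),
                   frequency = rowMeans(sub),
                   n = length(members))
  }, .id = "group")
}

#' Spot-spot correlation and weighted topological overlap
#'
#' Pearson correlations between spot profiles across accessions, and the
#' signed weighted topological overlap
#' `wto_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - |a_ij|)` with
#' `a` the correlation matrix (diagonal excluded from the sum and from the
#' connectivities `k_i = sum_{k != i} |a_ik|`).
#'
#' @param profiles A `spot_profiles` object (or a spots x accessions matrix).
#' @return List with `correlation` and `wto` matrices; spots with constant
#'   profiles get `NA` rows/columns.
#' @export
spot_correlation_wto <- function(profiles) {
  prof <- if (inherits(profiles, "spot_profiles")) profiles$profiles else as.matrix(profiles)
  if (nrow(prof) < 2) rlang::abort("need at least 2 spots")
  if (ncol(prof) < 3) rlang::abort("need at least 3 accessions")
  sds <- apply(prof, 1, sd)
  constant <- sds == 0
  if (any(constant)) {
    rlang::warn(paste0("constant spot profile(s), reported as missing: ",
                       paste(rownames(prof)[constant], collapse = ", ")))
  }
  a <- suppressWarnings(cor(t(prof)))
  a[constant, ] <- NA
  a[, constant] <- NA
  diag(a) <- 1
  n <- nrow(a)
  wto <- matrix(NA_real_, n, n, dimnames = dimnames(a))
  ok <- which(!constant)
  k <- rowSums(abs(a), na.rm = TRUE) - 1
  for (i in ok) for (j in ok) {
    others <- setdiff(ok, c(i, j))
    s <- sum(a[i, others] * a[others, j])
    wto[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - abs(a[i, j]))
  }
  list(correlation = a, wto = wto)
}

#' Spot implication graph
#'
#' Connects spots that tend to appear together across accessions: an
#' undirected edge joins spots whose call vectors have a Jaccard index of at
#' least `tau`.
#'
#' @param profiles A `spot_profiles` object (its call matrix is used) or a
#'   logical spots x accessions matrix.
#' @param tau Jaccard threshold in (0, 1] (default 0.25).
#' @param accession_ids Optional accession subset (per-group graphs).
#' @return An [igraph::igraph] with vertex per spot and edge attribute
#'   `jaccard`; spots never called are isolated nodes.
#' @export
implication_graph <- function(profiles, tau = 0.25, accession_ids = NULL) {
  calls <- if (inherits(profiles, "spot_profiles")) profiles$calls else as.matrix(profiles)
  if (tau <= 0 || tau > 1) rlang::abort("tau must lie in (0, 1]")
  if (!is.null(accession_ids)) calls <- calls[, accession_ids, drop = FALSE]
  j <- jaccard_columns(t(calls))
  adj <- j >= tau
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(gr)
  igraph::E(gr)$jaccard <- j[cbind(match(ends[, 1], rownames(j)),
                                   match(ends[, 2], rownames(j)))]
  gr
}

#' Chromosome-wise distribution of spot member SNPs
#'
#' @param spotmap A `spot_map`.
#' @param g The [snp_geno] (or `snp_scores`) carrying chrom/pos annotations.
#' @return Tibble with `spot`, `chrom`, `n_snps`, and a `pos` list-column of
#'   member positions.
#' @export
chromosome_distribution <- function(spotmap, g) {
  stopifnot(inherits(spotmap, "spot_map"))
  ann <- tibble::tibble(snp_id = g$snp_ids, chrom = g$chrom, pos = g$pos)
  purrr::map_dfr(seq_len(nrow(spotmap$spots)), function(i) {
    snps <- spotmap$spots$snp_ids[[i]]
    sub <- ann[ann$snp_id %in% snps, ]
    if (nrow(sub) == 0) return(tibble::tibble())
    sub |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(n_snps = dplyr::n(), pos = list(sort(.data$pos)),
                       .groups = "drop") |>
      dplyr::mutate(spot = spotmap$spots$spot[i], .before = 1)
  })
}
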