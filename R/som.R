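#' Train a batch self-organizing map over SNP-score profiles
#'
#' Distributes SNP profiles (rows of the score matrix) over a rectangular
#' grid of `grid_rows x grid_cols` units ("meta-SNPs") by minimizing the
#' Euclidean distance between each SNP profile and its best-matching unit
#' (BMU). Training is batch: per epoch every SNP is mapped to its BMU, then
#' every unit weight is replaced by the Gaussian-neighborhood-weighted mean
#' of the mapped profiles. The neighborhood radius decays linearly from
#' `radius_init` (default `max(grid dims)/2`) to `radius_final` (default 1)
#' over the epochs. Weights are initialized linearly on the plane of the
#' first two principal components of the SNP profiles, which makes training
#' deterministic up to the PCA sign convention; `init = "random"` samples
#' profiles instead (seeded).
#'
#' @param s A `snp_scores` object from [compute_snp_scores()].
#' @param grid_rows,grid_cols Grid dimensions (default 50 x 50, K = 2500).
#' @param epochs Number of batch epochs (default 20).
#' @param radius_init,radius_final Neighborhood radius schedule.
#' @param init `"pca"` (linear initialization) or `"random"`.
#' @param seed Integer seed (used by random init and kept for provenance).
#' @return A `snp_som` object: `weights` (K x accessions), `assignment`
#'   (named unit index per SNP), `qe` (quantization error per epoch), grid
#'   dimensions, parameters, and the SNP/accession annotations.
#' @export
train_som <- function(s, grid_rows = 50, grid_cols = 50, epochs = 20,
                      radius_init = NULL, radius_final = 1,
                      init = c("pca", "random"), seed = 1) {
  stopifnot(inherits(s, "snp_scores"))
  init <- match.arg(init)
  X <- s$scores
  n <- nrow(X)
  m <- ncol(X)
  if (n < 1) rlang::abort("no SNPs to train on")
  if (m == 0) rlang::abort("score matrix has no accessions")
  if (grid_rows < 2 || grid_cols < 2) rlang::abort("grid must be at least 2 x 2")
  K <- grid_rows * grid_cols
  radius_init <- radius_init %||% (max(grid_rows, grid_cols) / 2)
  set.seed(seed)
  uc <- unit_coords(grid_rows, grid_cols)
  W <- som_init(X, uc, init)
  d2grid <- unit_grid_dist2(grid_rows, grid_cols)
  x2 <- rowSums(X^2)
  qe <- numeric(epochs)
  bmu <- rep(1L, n)
  radii <- if (epochs == 1) radius_final else
    seq(radius_init, radius_final, length.out = epochs)
  qe_of <- function(W, bmu) {
    mean(sqrt(pmax(x2 - 2 * rowSums(X * W[bmu, , drop = FALSE]) +
                     rowSums(W^2)[bmu], 0)))
  }
  for (e in seq_len(epochs)) {
    # assignment step; this BMU also prices the previous epoch's update
    bmu <- find_bmu(X, W)
    if (e > 1) qe[e - 1] <- qe_of(W, bmu)
    cnt <- tabulate(bmu, nbins = K)
    S <- matrix(0, K, m)
    Spart <- rowsum(X, group = bmu)
    S[as.integer(rownames(Spart)), ] <- Spart
    H <- exp(-d2grid / (2 * radii[e]^2))
    W <- (H %*% S) / as.vector(H %*% cnt)
  }
  bmu <- find_bmu(X, W)
  qe[epochs] <- qe_of(W, bmu)
  dimnames(W) <- list(NULL, s$accession_ids)
  structure(list(
    weights = W, grid_rows = grid_rows, grid_cols = grid_cols,
    assignment = setNames(bmu, s$snp_ids), qe = qe,
    snp_ids = s$snp_ids, chrom = s$chrom, pos = s$pos,
    accession_ids = s$accession_ids,
    params = list(epochs = epochs, radius_init = radius_init,
                  radius_final = radius_final, init = init, seed = seed)
  ), class = "snp_som")
}

som_init <- function(X, uc, init) {
  n <- nrow(X)
  m <- ncol(X)
  K <- nrow(uc)
  if (init == "random") {
    idx <- sample.int(n, K, replace = K > n)
    return(X[idx, , drop = FALSE])
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  # linear init on the first two principal axes of the profile cloud
  sv <- tryCatch(svd(Xc, nu = 0, nv = min(2, m)), error = function(e) NULL)
  a1 <- (uc$col - mean(uc$col)) / max(1, (max(uc$col) - 1) / 2)
  a2 <- (uc$row - mean(uc$row)) / max(1, (max(uc$row) - 1) / 2)
  W <- matrix(rep(center, each = K), K, m)
  if (!is.null(sv) && length(sv$d) >= 1 && sv$d[1] > 0) {
    sd1 <- sv$d[1] / sqrt(max(1, n - 1))
    W <- W + outer(a1 * sd1, sv$v[, 1])
    if (length(sv$d) >= 2 && sv$d[2] > 0) {
      sd2 <- sv$d[2] / sqrt(max(1, n - 1))
      W <- W + outer(a2 * sd2, sv$v[, 2])
    }
  }
  W
}

# Best-matching unit per SNP profile; ties go to the lowest unit index.
find_bmu <- function(X, W) {
  cross <- tcrossprod(X, W)            # n x K
  half_w2 <- rowSums(W^2) / 2
  max.col(sweep(cross, 2, half_w2), ties.method = "first")
}

#' @export
print.snp_som <- function(x, ...) {
  cat(sprintf("<snp_som> %d x %d grid (K = %d), %d SNPs, %d accessions, final QE %.4f\n",
              x$grid_rows, x$grid_cols, x$grid_rows * x$grid_cols,
              length(x$assignment), length(x$accession_ids),
              x$qe[length(x$qe)]))
  invisible(x)
}

#' Summarize a trained SOM
#'
#' @param x A `snp_som` object.
#' @param ... Unused.
#' @return One-row tibble with grid size, SNP/accession counts, epochs,
#'   final quantization error, and occupied-unit count.
#' @export
glance.snp_som <- function(x, ...) {
  tibble::tibble(
    grid_rows = x$grid_rows, grid_cols = x$grid_cols,
    k_units = x$grid_rows * x$grid_cols,
    n_snps = length(x$assignment),
    n_accessions = length(x$accession_ids),
    epochs = x$params$epochs,
    final_qe = x$qe[length(x$qe)],
    occupied_units = length(unique(x$assignment))
  )
}

#' Tidy SOM unit weights into long form
#'
#' @param x A `snp_som` object.
#' @param ... Unused.
#' @return A tibble with `unit`, `row`, `col`, `accession_id`, `emaf`,
#'   and `n_snps` (unit occupancy).
#' @export
tidy.snp_som <- function(x, ...) {
  uc <- unit_coords(x$grid_rows, x$grid_cols)
  occ <- tabulate(x$assignment, nbins = nrow(uc))
  tibble::tibble(
    unit = rep(uc$unit, times = ncol(x$weights)),
    row = rep(uc$row, times = ncol(x$weights)),
    col = rep(uc$col, times = ncol(x$weights)),
    accession_id = rep(colnames(x$weights), each = nrow(uc)),
    emaf = as.vector(x$weights),
    n_snps = rep(occ, times = ncol(x$weights))
  )
}

#' Read out the portrait of one accession
#'
#' The portrait is the accession's column of unit weights arranged on the
#' grid: cell (r, c) carries the eMAF of meta-SNP (r, c) in that accession.
#'
#' @param model A `snp_som` object.
#' @param accession_id One accession identifier.
#' @return A `som_portrait`: numeric `grid_rows x grid_cols` matrix with a
#'   `label` attribute.
#' @export
portrait <- function(model, accession_id) {
  stopifnot(inherits(model, "snp_som"))
  if (length(accession_id) != 1 || !accession_id %in% model$accession_ids) {
    rlang::abort(paste0("unknown accession: ", paste(accession_id, collapse = ", ")))
  }
  g <- unit_vector_to_grid(model$weights[, accession_id],
                           model$grid_rows, model$grid_cols)
  structure(g, label = accession_id, class = c("som_portrait", "matrix", "array"))
}

#' Mean portrait of a group of accessions
#'
#' Element-wise average of the member portraits, e.g., the mean landscape of
#' a geographic region.
#'
#' @param model A `snp_som` object.
#' @param accession_ids Non-empty character vector of accession identifiers.
#' @param label Label attached to the portrait (default collapses the ids).
#' @return A `som_portrait`.
#' @export
mean_portrait <- function(model, accession_ids, label = NULL) {
  stopifnot(inherits(model, "snp_som"))
  if (length(accession_ids) == 0) rlang::abort("empty accession subset")
  missing <- setdiff(accession_ids, model$accession_ids)
  if (length(missing) > 0) {
    rlang::abort(paste0("unknown accession(s): ", paste(missing, collapse = ", ")))
  }
  w <- rowMeans(model$weights[, accession_ids, drop = FALSE])
  g <- unit_vector_to_grid(w, model$grid_rows, model$grid_cols)
  structure(g, label = label %||% paste(accession_ids, collapse = "+"),
            class = c("som_portrait", "matrix", "array"))
}

#' @export
print.som_portrait <- function(x, ...) {
  cat(sprintf("<som_portrait> '%s' %d x %d, eMAF range [%.3f, %.3f]\n",
              attr(x, "label"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Tidy a portrait grid into long form
#'
#' @param x A `som_portrait`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `emaf`, `label`.
#' @export
tidy.som_portrait <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    emaf = as.vector(unclass(x)),
    label = attr(x, "label")
  )
}

#' Quantization error of a trained SOM
#'
#' Mean Euclidean distance of each SNP profile to its best-matching unit's
#' weight vector; the convergence diagnostic logged during training.
#'
#' @param model A `snp_som` object.
#' @param s The `snp_scores` the model was trained on.
#' @return A single non-negative number.
#' @export
quantization_error <- function(model, s) {
  stopifnot(inherits(model, "snp_som"), inherits(s, "snp_scores"))
  if (ncol(s$scores) != ncol(model$weights) || nrow(s$scores) != length(model$assignment)) {
    rlang::abort("score matrix dimensions do not match the model")
  }
  X <- s$scores
  bmu <- find_bmu(X, model$weights)
  mean(sqrt(pmax(rowSums(X^2) - 2 * rowSums(X * model$weights[bmu, , drop = FALSE]) +
                   rowSums(model$weights^2)[bmu], 0)))
}

#' Persist a SOM model as a plain-text directory
#'
#' Writes `weights.tsv` (unit x accession), `assignment.tsv` (snp_id, unit),
#' and `params.json`.
#'
#' @param model A `snp_som`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_som <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- tibble::as_tibble(model$weights)
  w <- dplyr::bind_cols(tibble::tibble(unit = seq_len(nrow(model$weights))), w)
  readr::write_tsv(w, file.path(dir, "weights.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(snp_id = names(model$assignment),
                   unit = unname(model$assignment),
                   chrom = model$chrom, pos = model$pos),
    file.path(dir, "assignment.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(model$params, list(grid_rows = model$grid_rows, grid_cols = model$grid_cols,
                         qe = model$qe)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
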