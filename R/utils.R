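# Internal helpers shared across modules.

# Row-major unit indexing: unit k = (row - 1) * grid_cols + col.
unit_coords <- function(grid_rows, grid_cols) {
  k <- seq_len(grid_rows * grid_cols)
  tibble::tibble(
    unit = k,
    row = (k - 1L) %/% grid_cols + 1L,
    col = (k - 1L) %% grid_cols + 1L
  )
}

# Squared Euclidean distances between all grid units (K x K).
unit_grid_dist2 <- function(grid_rows, grid_cols) {
  uc <- unit_coords(grid_rows, grid_cols)
  dr <- outer(uc$row, uc$row, "-")
  dc <- outer(uc$col, uc$col, "-")
  dr^2 + dc^2
}

# Reshape a length-K unit vector (row-major) into a grid_rows x grid_cols matrix.
unit_vector_to_grid <- function(x, grid_rows, grid_cols) {
  matrix(x, nrow = grid_rows, ncol = grid_cols, byrow = TRUE)
}

grid_to_unit_vector <- function(g) {
  as.vector(t(g))
}

# 8-connected components of a logical matrix. Returns an integer matrix with
# 0 for background and components numbered 1..n in first-encounter order.
connected_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (mask[r0, c0] && lab[r0, c0] == 0L) {
        nxt <- nxt + 1L
        queue <- matrix(c(r0, c0), ncol = 2)
        lab[r0, c0] <- nxt
        while (nrow(queue) > 0) {
          cur <- queue[1, , drop = TRUE]
          queue <- queue[-1, , drop = FALSE]
          for (dr in -1:1) for (dc in -1:1) {
            r <- cur[1] + dr
            c <- cur[2] + dc
            if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
                mask[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- nxt
              queue <- rbind(queue, c(r, c))
            }
          }
        }
      }
    }
  }
  lab
}

# Spot labels A, B, ..., Z, AA, AB, ... for arbitrary counts.
spot_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

# Shannon entropy (base 2) of the non-negative part of a profile, renormalized
# to sum one; zero when nothing is positive.
profile_entropy <- function(x) {
  p <- pmax(x, 0)
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

# Pairwise Jaccard index between columns of a logical matrix.
jaccard_columns <- function(m) {
  m <- m * 1
  inter <- crossprod(m)
  size <- diag(inter)
  uni <- outer(size, size, "+") - inter
  j <- inter / uni
  j[uni == 0] <- 0
  j
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
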