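#' One-way ANOVA phenotype map
#'
#' Per SOM unit, a one-way ANOVA F-test of the unit's weight values across
#' the phenotype categories; the map carries `-log10(p)`. Categories with
#' fewer than two accessions are excluded with a warning.
#'
#' @param model A `snp_som` object.
#' @param labels Categorical label per accession (named vector, or in the
#'   order of `model$accession_ids`).
#' @param name Phenotype name attached to the map.
#' @return A `phenotype_map`: grid of `-log10(p)` with attributes `phenotype`
#'   and `statistic = "anova"`.
#' @export
anova_map <- function(model, labels, name = "phenotype") {
  stopifnot(inherits(model, "snp_som"))
  labels <- align_labels(labels, model$accession_ids)
  keep <- !is.na(labels)
  labels <- factor(labels[keep])
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("excluding categories with < 2 accessions: ",
                       paste(small, collapse = ", ")))
    keep2 <- !labels %in% small
    labels <- droplevels(labels[keep2])
    keep[keep] <- keep2
  }
  if (nlevels(labels) < 2) rlang::abort("need at least 2 usable categories")
  W <- model$weights[, keep, drop = FALSE]
  f <- anova_f_rows(W, labels)
  grid <- unit_vector_to_grid(-log10(f$p), model$grid_rows, model$grid_cols)
  structure(grid, phenotype = name, statistic = "anova",
            class = c("phenotype_map", "matrix", "array"))
}

# Vectorized one-way ANOVA over the rows of a matrix (columns grouped by
# labels). Returns F statistics and p-values.
anova_f_rows <- function(W, labels) {
  labels <- factor(labels)
  n <- ncol(W)
  G <- nlevels(labels)
  ng <- as.vector(table(labels))
  grand <- rowMeans(W)
  gm <- t(rowsum(t(W), labels)) / rep(ng, each = nrow(W))
  ssb <- rowSums(sweep(gm, 1, grand, "-")^2 %*% diag(ng, G))
  sst <- rowSums(sweep(W, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- G - 1
  df2 <- n - G
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  f[ssw == 0 & ssb == 0] <- 0
  list(f = f, p = p, df1 = df1, df2 = df2)
}

align_labels <- function(labels, accession_ids) {
  if (!is.null(names(labels))) {
    out <- labels[accession_ids]
  } else {
    if (length(labels) != length(accession_ids)) {
      rlang::abort("labels must be named or match the accession count")
    }
    out <- labels
  }
  as.character(out)
}

#' Point-biserial phenotype correlation map
#'
#' Per SOM unit, the Pearson correlation between the unit's weight values and
#' a 0/1 phenotype indicator. Up to a single positive per-map scaling this is
#' the difference portrait between the indicated group and the rest.
#'
#' @param model A `snp_som` object.
#' @param indicator Binary (0/1 or logical) per accession, named or in model
#'   order.
#' @param name Phenotype name.
#' @return A `phenotype_map` with values in `[-1, 1]` and
#'   `statistic = "pointbiserial"`.
#' @export
pointbiserial_map <- function(model, indicator, name = "phenotype") {
  stopifnot(inherits(model, "snp_som"))
  if (!is.null(names(indicator))) indicator <- indicator[model$accession_ids]
  ind <- as.numeric(indicator)
  if (length(ind) != length(model$accession_ids)) {
    rlang::abort("indicator length must match the accession count")
  }
  if (!all(ind %in% c(0, 1))) rlang::abort("indicator must be binary 0/1")
  if (sum(ind) == 0 || sum(ind) == length(ind)) {
    rlang::abort("both indicator groups must be non-empty")
  }
  r <- suppressWarnings(as.vector(cor(t(model$weights), ind)))
  if (anyNA(r)) {
    rlang::warn("constant unit weight(s): correlation set to 0")
    r[is.na(r)] <- 0
  }
  grid <- unit_vector_to_grid(r, model$grid_rows, model$grid_cols)
  structure(grid, phenotype = name, statistic = "pointbiserial",
            class = c("phenotype_map", "matrix", "array"))
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat(sprintf("<phenotype_map> '%s' (%s), %d x %d, range [%.3f, %.3f]\n",
              attr(x, "phenotype"), attr(x, "statistic"), nrow(x), ncol(x),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a phenotype map into long form
#'
#' @param x A `phenotype_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `value`, `phenotype`, `statistic`.
#' @export
tidy.phenotype_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(unclass(x)),
    phenotype = attr(x, "phenotype"),
    statistic = attr(x, "statistic")
  )
}

#' Top phenotype-correlated SNPs
#'
#' Correlates each raw SNP-score row with a 0/1 indicator and returns the
#' top `n` SNPs by absolute correlation, annotated with their SOM unit,
#' spot label (when a spot map is given), coordinates, and Benjamini-Hochberg
#' q-values (computed over all SNPs).
#'
#' @param s A `snp_scores` object.
#' @param indicator Binary 0/1 per accession, named or in score-column order.
#' @param model Optional `snp_som` for unit annotation.
#' @param spotmap Optional `spot_map` for spot annotation.
#' @param n Number of SNPs to report (default 100).
#' @return Tibble with `snp_id`, `chrom`, `pos`, `r`, `q`, and (when
#'   available) `unit_row`, `unit_col`, `spot`; sorted by `|r|` descending.
#' @export
top_correlated_snps <- function(s, indicator, model = NULL, spotmap = NULL, n = 100) {
  stopifnot(inherits(s, "snp_scores"))
  if (n < 1) rlang::abort("n must be >= 1")
  if (!is.null(names(indicator))) indicator <- indicator[s$accession_ids]
  ind <- as.numeric(indicator)
  if (!all(ind %in% c(0, 1))) rlang::abort("indicator must be binary 0/1")
  if (n > nrow(s$scores)) {
    rlang::warn(sprintf("n = %d exceeds the SNP count; returning all %d SNPs",
                        n, nrow(s$scores)))
    n <- nrow(s$scores)
  }
  r <- suppressWarnings(as.vector(cor(t(s$scores), ind)))
  r[is.na(r)] <- 0
  nn <- length(ind)
  tstat <- r * sqrt(pmax(nn - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = max(nn - 2, 1))
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(snp_id = s$snp_ids, chrom = s$chrom, pos = s$pos,
                        r = r, q = q)
  if (!is.null(model)) {
    uc <- unit_coords(model$grid_rows, model$grid_cols)
    unit <- unname(model$assignment[out$snp_id])
    out$unit_row <- uc$row[unit]
    out$unit_col <- uc$col[unit]
    if (!is.null(spotmap)) {
      spot_of_unit <- rep(NA_character_, nrow(uc))
      for (i in seq_len(nrow(spotmap$spots))) {
        spot_of_unit[spotmap$spots$units[[i]]] <- spotmap$spots$spot[i]
      }
      out$spot <- spot_of_unit[unit]
    }
  }
  out <- out[order(-abs(out$r)), ]
  head(out, n)
}

#' Group-wise one-vs-rest ANOVA portraits
#'
#' For each group (e.g., country), a grid where every unit carries the
#' `-log10(p)` of a two-group ANOVA contrasting the group's accessions with
#' all others: regions of large group-specific score variance light up.
#'
#' @param model A `snp_som` object.
#' @param group_labels Group label per accession (named or in model order).
#' @param min_members Minimum group size rendered (default 2); smaller groups
#'   are skipped with a warning.
#' @return Named list of `phenotype_map` objects, one per rendered group.
#' @export
group_anova_portraits <- function(model, group_labels, min_members = 2) {
  stopifnot(inherits(model, "snp_som"))
  labels <- align_labels(group_labels, model$accession_ids)
  groups <- sort(unique(labels[!is.na(labels)]))
  out <- list()
  for (g in groups) {
    ind <- labels == g
    if (sum(ind, na.rm = TRUE) < min_members) {
      rlang::warn(sprintf("skipping group '%s' with < %d members", g, min_members))
      next
    }
    if (all(ind, na.rm = TRUE)) {
      rlang::abort(sprintf("group '%s' equals the full accession set; one-vs-rest undefined", g))
    }
    two <- factor(ifelse(ind, g, ".rest"))
    keep <- !is.na(labels)
    f <- anova_f_rows(model$weights[, keep, drop = FALSE], two[keep])
    grid <- unit_vector_to_grid(-log10(f$p), model$grid_rows, model$grid_cols)
    out[[g]] <- structure(grid, phenotype = g, statistic = "anova",
                          class = c("phenotype_map", "matrix", "array"))
  }
  out
}

#' One-vs-rest indicators for a categorical phenotype
#'
#' @param x Categorical vector (e.g., utilization), optionally named.
#' @return Named list of 0/1 vectors, one per category level.
#' @export
one_vs_rest <- function(x) {
  nms <- names(x)
  x <- as.character(x)
  lv <- sort(unique(x[!is.na(x)]))
  out <- lapply(lv, function(l) as.numeric(x == l))
  if (!is.null(nms)) out <- lapply(out, setNames, nms)
  setNames(out, lv)
}
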