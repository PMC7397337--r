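# Shared fixtures, built in code at test time.

# A fresh scratch directory under the session tempdir (cleaned up on exit).
fixture_dir <- function() {
  d <- tempfile("snpsom_fixture_")
  dir.create(d, recursive = TRUE)
  d
}

# Write a tiny genotype TSV and return its path.
write_tiny_genotype_tsv <- function(dir = fixture_dir()) {
  path <- file.path(dir, "tiny.tsv")
  writeLines(c(
    "snp_id\tchrom\tpos\tacc1\tacc2",
    "s1\t1\t100\t0\t1",
    "s2\t1\t200\t2\t1",
    "s3\t2\t50\t1\t0"
  ), path)
  path
}

# Minimal VCF with two biallelic records (and optionally one triallelic).
write_tiny_vcf <- function(dir = fixture_dir(), triallelic = FALSE) {
  path <- file.path(dir, "tiny.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tacc1\tacc2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "2\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t./."
  )
  if (triallelic) {
    lines <- c(lines, "3\t300\trs3\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2")
  }
  writeLines(lines, path)
  path
}

# A genotype object with known codes; accession count defaults to 4.
toy_geno <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  snp_geno(codes,
           snp_ids = paste0("s", seq_len(n)),
           chrom = chrom %||% rep("1", n),
           pos = pos %||% seq_len(n) * 100,
           accession_ids = paste0("a", seq_len(ncol(codes))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype matrix with dimnames, for property checks.
random_geno <- function(n_snps, n_acc, seed = 1) {
  set.seed(seed)
  toy_geno(matrix(sample(0:2, n_snps * n_acc, replace = TRUE), n_snps, n_acc))
}

# Scores -> trained model on a small grid, shared by several suites.
small_vinelike_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_vinelike(n_snps = 800, n_per_pop = 10, seed = 42)
      o <- suppressWarnings(orient_minor_allele(sim$genotype))
      s <- compute_snp_scores(o$genotype, o$maf)
      m <- train_som(s, 15, 15, epochs = 10, seed = 42)
      cache <<- list(sim = sim, scores = s, model = m)
    }
    cache
  }
})

# Brute-force mean min-distance over all units (quantization error oracle).
# X: SNPs x accessions, W: units x accessions.
qe_oracle <- function(X, W) {
  mean(vapply(seq_len(nrow(X)), function(i) {
    sqrt(min(rowSums(sweep(W, 2, X[i, ])^2)))
  }, numeric(1)))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

# A hand-built model whose weights are set directly, for geometric checks.
model_from_weights <- function(W, grid_rows, grid_cols, assignment = NULL) {
  K <- grid_rows * grid_cols
  stopifnot(nrow(W) == K)
  if (is.null(colnames(W))) colnames(W) <- paste0("a", seq_len(ncol(W)))
  assignment <- assignment %||%
    setNames(rep(seq_len(K), length.out = K), paste0("s", seq_len(K)))
  structure(list(
    weights = W, grid_rows = grid_rows, grid_cols = grid_cols,
    assignment = assignment, qe = 0,
    snp_ids = names(assignment),
    chrom = rep("1", length(assignment)),
    pos = seq_along(assignment),
    accession_ids = colnames(W),
    params = list(epochs = 0, radius_init = 1, radius_final = 1,
                  init = "pca", seed = 1)
  ), class = "snp_som")
}
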