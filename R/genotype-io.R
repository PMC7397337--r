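#' Genotype matrix container
#'
#' A `snp_geno` object holds a trinary-coded biallelic genotype matrix
#' (SNPs in rows, accessions in columns; codes 0 = homozygous major,
#' 1 = heterozygous, 2 = homozygous minor, `NA` = missing) together with
#' per-SNP chromosome labels and 1-based positions.
#'
#' @param codes Integer matrix, SNPs x accessions, values in `{0, 1, 2, NA}`.
#' @param snp_ids Character vector of unique SNP identifiers.
#' @param chrom Character vector of chromosome labels, one per SNP.
#' @param pos Integer vector of 1-based positions, one per SNP.
#' @param accession_ids Character vector of unique accession identifiers.
#'
#' @return An object of class `snp_geno`.
#' @export
snp_geno <- function(codes, snp_ids, chrom, pos, accession_ids) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  snp_ids <- as.character(snp_ids)
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(snp_ids)) {
    rlang::abort(paste0("duplicate snp_id: ",
                        paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(accession_ids)) {
    rlang::abort("duplicate accession ids")
  }
  if (length(snp_ids) != nrow(codes) || length(accession_ids) != ncol(codes)) {
    rlang::abort("identifier lengths do not match the code matrix dimensions")
  }
  if (length(chrom) != nrow(codes) || length(pos) != nrow(codes)) {
    rlang::abort("chrom/pos must have one entry per SNP")
  }
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("genotype code not in {0,1,2} at SNP '%s', accession '%s'",
                         snp_ids[idx[1]], accession_ids[idx[2]]))
  }
  dimnames(codes) <- list(snp_ids, accession_ids)
  structure(
    list(codes = codes, snp_ids = snp_ids, chrom = as.character(chrom),
         pos = as.integer(pos), accession_ids = accession_ids),
    class = "snp_geno"
  )
}

#' @export
print.snp_geno <- function(x, ...) {
  cat(sprintf("<snp_geno> %d SNPs x %d accessions (%.1f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.snp_geno <- function(x) dim(x$codes)

#' Tidy a genotype matrix into long form
#'
#' @param x A [snp_geno] object.
#' @param ... Unused.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `accession_id`,
#'   `code`.
#' @export
tidy.snp_geno <- function(x, ...) {
  tibble::tibble(
    snp_id = rep(x$snp_ids, times = ncol(x$codes)),
    chrom = rep(x$chrom, times = ncol(x$codes)),
    pos = rep(x$pos, times = ncol(x$codes)),
    accession_id = rep(x$accession_ids, each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
}

#' Read a genotype table from TSV or VCF
#'
#' TSV input must carry the columns `snp_id`, `chrom`, `pos` followed by one
#' column per accession holding codes in `{0, 1, 2}` (`NA` for missing).
#' VCF input must be biallelic; diploid GT fields are translated as
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA` (phased
#' separators are accepted).
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension when
#'   omitted.
#' @return A [snp_geno] object.
#' @export
read_genotype_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  g <- if (format == "vcf") read_genotype_vcf(path) else read_genotype_tsv(path)
  rlang::inform(sprintf("read %d SNPs x %d accessions from %s",
                        nrow(g$codes), ncol(g$codes), basename(path)))
  g
}

read_genotype_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(tab))) {
    rlang::abort("genotype TSV must have columns snp_id, chrom, pos before the accession codes")
  }
  acc <- setdiff(names(tab), need)
  if (length(acc) == 0) rlang::abort("genotype TSV has no accession columns")
  codes <- as.matrix(tab[acc])
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-{0,1,2} genotype code at row %d, column '%s'",
                         idx[1], acc[idx[2]]))
  }
  snp_geno(codes, tab$snp_id, tab$chrom, tab$pos, acc)
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    i <- which(multi)[1]
    rlang::abort(sprintf("multiallelic VCF record at %s:%s", fix[i, "CHROM"], fix[i, "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code_one <- function(x) {
    x <- sub(":.*", "", x)
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  codes <- apply(gt, 2, code_one)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(gt))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  snp_geno(codes, ids, fix[, "CHROM"], as.integer(fix[, "POS"]), colnames(gt))
}

#' Write a genotype matrix as TSV
#'
#' Emits the tab-separated layout [read_genotype_table()] reads back
#' (`snp_id`, `chrom`, `pos`, one column per accession, `NA` for missing).
#'
#' @param g A [snp_geno] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  tab <- tibble::as_tibble(g$codes)
  tab <- dplyr::bind_cols(
    tibble::tibble(snp_id = g$snp_ids, chrom = g$chrom, pos = g$pos), tab
  )
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read an accession metadata table
#'
#' Expects a TSV with an `accession_id` column; a `utilization` column, when
#' present, is normalized case-insensitively to the levels `table`, `wine`,
#' `double`, `unknown`. All other columns pass through as labels.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with one row per accession.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tab) == 0) rlang::abort("metadata file is empty")
  if (!"accession_id" %in% names(tab)) {
    rlang::abort("metadata must contain an accession_id column")
  }
  if ("utilization" %in% names(tab)) {
    tab$utilization <- normalize_utilization(tab$utilization)
  }
  tab
}

normalize_utilization <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  known <- c("table", "wine", "double", "unknown")
  x[!x %in% known] <- "unknown"
  factor(x, levels = known)
}

#' Orient codes so the minor allele is coded upward
#'
#' Computes the per-SNP allele frequency of the allele coded upward
#' (mean code / 2, missing codes ignored) and flips codes `c -> 2 - c` for
#' SNPs where that frequency exceeds one half, so that after orientation
#' every SNP's minor allele frequency (MAF) lies in `[0, 0.5]`. A frequency of
#' exactly 0.5 keeps the input orientation (with a warning).
#'
#' @param g A [snp_geno] object.
#' @return A list with elements `genotype` (oriented [snp_geno]) and `maf`
#'   (named numeric vector of per-SNP MAF).
#' @export
orient_minor_allele <- function(g) {
  stopifnot(inherits(g, "snp_geno"))
  n_obs <- rowSums(!is.na(g$codes))
  if (any(n_obs == 0)) {
    rlang::abort(paste0("SNP(s) with all genotypes missing: ",
                        paste(g$snp_ids[n_obs == 0], collapse = ", ")))
  }
  freq <- rowMeans(g$codes, na.rm = TRUE) / 2
  flip <- freq > 0.5
  ties <- abs(freq - 0.5) < .Machine$double.eps^0.5
  if (any(ties)) {
    rlang::warn(sprintf("%d SNP(s) with allele frequency exactly 0.5; input orientation kept",
                        sum(ties)))
  }
  codes <- g$codes
  codes[flip, ] <- 2L - codes[flip, , drop = FALSE]
  maf <- freq
  maf[flip] <- 1 - freq[flip]
  names(maf) <- g$snp_ids
  out <- g
  out$codes <- codes
  list(genotype = out, maf = maf)
}

#' Compute centered SNP-scores (eMAF units)
#'
#' Centers each oriented SNP-code by twice its minor allele frequency:
#' `score = code - 2 * MAF`, giving `-2 MAF` for homozygous major, `1 - 2 MAF`
#' for heterozygous and `2 (1 - MAF)` for homozygous minor genotypes. Each SNP
#' row then has mean zero over accessions; group averages of these scores
#' measure the excess minor-allele frequency (eMAF) of a SNP set in one
#' accession relative to the whole population. Missing codes are mean-imputed
#' (score 0).
#'
#' @param g An oriented [snp_geno] object.
#' @param maf Named per-SNP MAF vector as returned by [orient_minor_allele()].
#' @return A `snp_scores` object: list with `scores` (numeric matrix,
#'   SNPs x accessions), `maf`, and the SNP/accession annotations.
#' @export
compute_snp_scores <- function(g, maf) {
  stopifnot(inherits(g, "snp_geno"))
  if (length(maf) != nrow(g$codes)) rlang::abort("maf length must equal the SNP count")
  scores <- sweep(g$codes + 0, 1, 2 * maf, "-")
  scores[is.na(scores)] <- 0
  structure(
    list(scores = scores, maf = as.numeric(maf), snp_ids = g$snp_ids,
         chrom = g$chrom, pos = g$pos, accession_ids = g$accession_ids),
    class = "snp_scores"
  )
}

#' @export
print.snp_scores <- function(x, ...) {
  cat(sprintf("<snp_scores> %d SNPs x %d accessions (eMAF units)\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' @export
dim.snp_scores <- function(x) dim(x$scores)

#' Drop monomorphic SNPs from a genotype matrix
#'
#' Monomorphic SNPs (MAF 0) carry all-zero scores; they cannot affect the
#' self-organization but inflate unit occupancy.
#'
#' @param g A [snp_geno] object.
#' @param maf Per-SNP MAF vector.
#' @return A list with the filtered `genotype` and `maf`.
#' @export
drop_monomorphic <- function(g, maf) {
  keep <- maf > 0
  out <- g
  out$codes <- g$codes[keep, , drop = FALSE]
  out$snp_ids <- g$snp_ids[keep]
  out$chrom <- g$chrom[keep]
  out$pos <- g$pos[keep]
  list(genotype = out, maf = maf[keep])
}
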