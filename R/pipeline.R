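#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable parameter of the
#' pipeline; pass overrides to replace individual entries.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A named list (class `snpsom_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genotype = NULL, metadata = NULL, outdir = "snpsom_out", seed = 1,
    drop_monomorphic = FALSE,
    som = list(grid_rows = 50, grid_cols = 50, epochs = 20,
               radius_final = 1, init = "pca"),
    spots = list(q_high = 0.98, min_size = 4, summary_stat = "max",
                 call_quantile = 0.98, implication_tau = 0.25),
    phenotype = list(column = "utilization"),
    diversity = list(net_threshold = 0.5, linkage = "average",
                     group_column = "region"),
    pseudotime = list(enabled = TRUE, k = 15, n_floods = 100, q = 0.8,
                      n_walks = 500, epsilon = 0.02, trunk_threshold = 0.6,
                      root_population = NULL),
    stages = c("score", "som", "spots", "phenotype", "diversity", "pseudotime")
  )
  overrides <- list(...)
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = c("snpsom_config", "list"))
}

#' Run the portrayal pipeline
#'
#' Executes load -> orient -> score -> SOM training -> portraits -> spot
#' segmentation -> phenotype maps -> diversity -> pseudotime, writing every
#' artifact under `config$outdir` together with a copy of the configuration
#' and a checksummed manifest. Identical configuration and seed give an
#' identical manifest.
#'
#' @param config A list from [pipeline_config()] (paths in `genotype` /
#'   `metadata`, or ready objects passed via `genotype_object` /
#'   `metadata_object`).
#' @return Invisibly, a list with the fitted objects and the manifest tibble.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "snpsom_config")) config else do.call(pipeline_config, config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  log_line <- function(...) {
    rlang::inform(sprintf("[snpsom seed=%s] %s", cfg$seed, sprintf(...)))
  }
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  g <- stage("load", {
    if (!is.null(cfg$genotype_object)) cfg$genotype_object
    else read_genotype_table(cfg$genotype)
  })
  md <- stage("load", {
    if (!is.null(cfg$metadata_object)) cfg$metadata_object
    else if (!is.null(cfg$metadata)) read_metadata(cfg$metadata)
    else NULL
  })
  oriented <- stage("orient", orient_minor_allele(g))
  if (isTRUE(cfg$drop_monomorphic)) {
    kept <- drop_monomorphic(oriented$genotype, oriented$maf)
    oriented <- list(genotype = kept$genotype, maf = kept$maf)
  }
  s <- stage("score", compute_snp_scores(oriented$genotype, oriented$maf))
  log_line("scored %d SNPs x %d accessions", nrow(s$scores), ncol(s$scores))

  model <- stage("som", train_som(
    s, grid_rows = cfg$som$grid_rows, grid_cols = cfg$som$grid_cols,
    epochs = cfg$som$epochs, radius_final = cfg$som$radius_final,
    init = cfg$som$init, seed = cfg$seed))
  write_som(model, file.path(cfg$outdir, "som"))
  readr::write_tsv(glance(model), file.path(cfg$outdir, "som_summary.tsv"),
                   progress = FALSE)
  log_line("trained %dx%d SOM, final QE %.4f", model$grid_rows,
           model$grid_cols, model$qe[length(model$qe)])

  out <- list(config = cfg, genotype = oriented$genotype, maf = oriented$maf,
              scores = s, model = model)

  if ("spots" %in% cfg$stages) {
    sm <- stage("spots", spot_segmentation(
      model, q_high = cfg$spots$q_high, min_size = cfg$spots$min_size,
      summary_stat = cfg$spots$summary_stat))
    prof <- stage("spots", spot_profiles(sm, model,
                                         call_quantile = cfg$spots$call_quantile))
    write_spot_map(sm, file.path(cfg$outdir, "spots"))
    readr::write_tsv(tidy(prof), file.path(cfg$outdir, "spots", "profiles.tsv"),
                     progress = FALSE)
    readr::write_tsv(prof$accession_stats,
                     file.path(cfg$outdir, "spots", "accession_stats.tsv"),
                     progress = FALSE)
    log_line("segmented %d spot(s)", nrow(sm$spots))
    out$spotmap <- sm
    out$spot_profiles <- prof
  }

  pheno_col <- cfg$phenotype$column
  if ("phenotype" %in% cfg$stages && !is.null(md) && pheno_col %in% names(md)) {
    dir.create(file.path(cfg$outdir, "phenotype"), showWarnings = FALSE)
    labels <- setNames(as.character(md[[pheno_col]]), md$accession_id)
    maps <- stage("phenotype", {
      am <- anova_map(model, labels, name = pheno_col)
      inds <- one_vs_rest(labels)
      pbs <- lapply(names(inds), function(nm)
        pointbiserial_map(model, inds[[nm]], name = nm))
      names(pbs) <- names(inds)
      tops <- lapply(names(inds), function(nm)
        top_correlated_snps(s, inds[[nm]], model = model,
                            spotmap = out$spotmap, n = 100))
      names(tops) <- names(inds)
      list(anova = am, pointbiserial = pbs, top_snps = tops)
    })
    readr::write_tsv(tidy(maps$anova),
                     file.path(cfg$outdir, "phenotype", "anova_map.tsv"),
                     progress = FALSE)
    for (nm in names(maps$pointbiserial)) {
      readr::write_tsv(tidy(maps$pointbiserial[[nm]]),
                       file.path(cfg$outdir, "phenotype",
                                 paste0("pointbiserial_", nm, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(maps$top_snps[[nm]],
                       file.path(cfg$outdir, "phenotype",
                                 paste0("top_snps_", nm, ".tsv")),
                       progress = FALSE)
    }
    out$phenotype_maps <- maps
  }

  if ("diversity" %in% cfg$stages) {
    div <- stage("diversity", {
      corr <- portrait_correlation(model)
      pca <- pca_accessions(model, n_components = 3)
      net <- similarity_net(corr, threshold = cfg$diversity$net_threshold)
      mst <- minimum_spanning_tree(corr)
      hc <- hierarchical_tree(corr, linkage = cfg$diversity$linkage)
      list(corr = corr, pca = pca, net = net, mst = mst, hc = hc)
    })
    dir.create(file.path(cfg$outdir, "diversity"), showWarnings = FALSE)
    readr::write_tsv(div$pca$coords,
                     file.path(cfg$outdir, "diversity", "pca.tsv"),
                     progress = FALSE)
    write_graph_tsv(div$net, file.path(cfg$outdir, "diversity", "similarity_net.tsv"))
    write_graph_tsv(div$mst, file.path(cfg$outdir, "diversity", "mst.tsv"))
    write_newick(div$hc, file.path(cfg$outdir, "diversity", "dendrogram.nwk"))
    gcol <- cfg$diversity$group_column
    if (!is.null(md) && gcol %in% names(md)) {
      labels <- setNames(as.character(md[[gcol]]), md$accession_id)
      sil <- stage("diversity", cluster_stability(div$corr, labels))
      readr::write_tsv(sil, file.path(cfg$outdir, "diversity", "silhouette.tsv"),
                       progress = FALSE)
      div$silhouette <- sil
    }
    out$diversity <- div
  }

  if ("pseudotime" %in% cfg$stages && isTRUE(cfg$pseudotime$enabled)) {
    traj <- stage("pseudotime", {
      corr <- out$diversity$corr %||% portrait_correlation(model)
      gr <- knn_graph(corr, k = cfg$pseudotime$k)
      roots <- pipeline_roots(cfg, md, model)
      pt <- flood_pseudotime(gr, roots, n_floods = cfg$pseudotime$n_floods,
                             q = cfg$pseudotime$q, seed = cfg$seed)
      tips <- propose_tips(gr, pt, seed = cfg$seed)
      if (length(tips) == 0) tips <- list(tip1 = names(pt)[which.max(pt)])
      assign_branches(gr, pt, tips, root_ids = roots,
                      n_walks = cfg$pseudotime$n_walks,
                      epsilon = cfg$pseudotime$epsilon,
                      trunk_threshold = cfg$pseudotime$trunk_threshold,
                      seed = cfg$seed)
    })
    dir.create(file.path(cfg$outdir, "pseudotime"), showWarnings = FALSE)
    readr::write_tsv(traj$assignments,
                     file.path(cfg$outdir, "pseudotime", "trajectory.tsv"),
                     progress = FALSE)
    jsonlite::write_json(traj$tree,
                         file.path(cfg$outdir, "pseudotime", "branch_tree.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("pseudotime over %d accessions, %d tip(s)",
             nrow(traj$assignments), length(traj$tips))
    out$trajectory <- traj
  }

  manifest <- build_manifest(cfg$outdir)
  readr::write_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"),
                   progress = FALSE)
  out$manifest <- manifest
  invisible(out)
}

pipeline_roots <- function(cfg, md, model) {
  rp <- cfg$pseudotime$root_population
  if (!is.null(rp) && !is.null(md)) {
    col <- cfg$diversity$group_column
    roots <- md$accession_id[md[[col]] %in% rp]
    if (length(roots) > 0) return(roots)
  }
  if (!is.null(cfg$pseudotime$root_ids)) return(cfg$pseudotime$root_ids)
  # fall back to the most "central" accession: highest mean portrait correlation
  corr <- portrait_correlation(model)
  colnames(corr)[which.max(colMeans(corr, na.rm = TRUE))]
}

write_spot_map <- function(sm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nr <- nrow(sm$label_grid)
  nc <- ncol(sm$label_grid)
  letters_by_idx <- c(NA_character_, sm$spots$spot)[as.vector(sm$label_grid) + 1L]
  readr::write_tsv(tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    spot = letters_by_idx,
    summary_emaf = as.vector(sm$summary)
  ), file.path(dir, "label_grid.tsv"), progress = FALSE)
  snp_lists <- tidyr::unnest(
    dplyr::select(sm$spots, "spot", "snp_ids"), "snp_ids")
  readr::write_tsv(snp_lists, file.path(dir, "spot_snps.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(thresholds = sm$thresholds, spots = dplyr::select(
      sm$spots, "spot", "size", "n_snps", "centroid_row", "centroid_col")),
    file.path(dir, "spots.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_graph_tsv <- function(gr, path) {
  el <- igraph::as_edgelist(gr)
  tab <- tibble::tibble(from = el[, 1], to = el[, 2])
  for (attr in igraph::edge_attr_names(gr)) {
    tab[[attr]] <- igraph::edge_attr(gr, attr)
  }
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

build_manifest <- function(outdir) {
  files <- sort(setdiff(
    list.files(outdir, recursive = TRUE),
    "manifest.tsv"))
  sums <- tools::md5sum(file.path(outdir, files))
  tibble::tibble(file = files, md5 = unname(sums))
}

#' Write a simulated fixture from a simulation spec
#'
#' Thin wrapper pairing [simulate_vinelike()] (or a custom tree) with
#' [write_fixture()]: the `simulate` pipeline subcommand.
#'
#' @param dir Output directory.
#' @param n_snps,n_per_pop,f,n_causal,effect,seed Passed to
#'   [simulate_vinelike()].
#' @param tree Optional custom `pop_tree` replacing the vinelike cross.
#' @return Invisibly, the simulation list (with files written under `dir`).
#' @export
simulate_command <- function(dir, n_snps = 4000, n_per_pop = 30, f = 0.08,
                             n_causal = 0, effect = 0.4, seed = 1, tree = NULL) {
  sim <- if (is.null(tree)) {
    simulate_vinelike(n_snps = n_snps, n_per_pop = n_per_pop, f = f,
                      n_causal = n_causal, effect = effect, seed = seed)
  } else {
    base <- simulate_genotypes(tree, n_snps = n_snps, n_per_pop = n_per_pop,
                               seed = seed)
    pops <- unique(base$truth$populations)
    probs <- setNames(rep(list(c(table = 0.5, wine = 0.5)), length(pops)), pops)
    simulate_phenotypes(base, probs, n_causal = n_causal, effect = effect,
                        seed = seed + 1000L)
  }
  write_fixture(sim, dir)
  invisible(sim)
}
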