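# Pipeline configuration and the end-to-end orchestrator.

#' Default pipeline configuration
#'
#' Every stage parameter named in the module documentation, with the
#' package defaults. A config is a plain nested list, serializable to YAML
#' with \code{\link{write_config}}; unknown keys are rejected on read.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sim = list(n_cells = 391L, dropout_rate = 0.05, nb_dispersion = 0.4),
    qc = list(min_genes_detected = 100L, min_total = 1000L),
    hvg = list(n_bins = 20L, z_cutoff = 1, mean_min = 0.1),
    pca = list(k = 10L),
    dbscan = list(eps = NULL, min_pts = 5L, n_pcs = 10L),
    markers = list(min_log_fc = 1, q_max = 0.05),
    assign = list(q_max = 0.05),
    cellcycle = list(n_bins = 25L, bg_per_gene = 50L),
    gsea = list(n_perm = 200L, weight = 1),
    trajectory = list(k_neighbors = 30L, n_comps = 10L,
                      dynamic_q = 0.05),
    coexpr = list(n_perm = 200L, min_expr_frac = 0.1, delta = 0.5,
                  include_stem = FALSE),
    project = list(q_threshold = 0.05, max_gap = 50000L))
}

check_config_keys <- function(cfg, ref = default_config(), path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config keys: ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && length(names(ref[[nm]])))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected before any stage runs. read(write(x)) is the identity.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param cfg a config list.
#' @export
write_config <- function(cfg, path) {
  check_config_keys(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# tiny FNV-1a hash for manifest provenance (hex string)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes simulate, preprocess, cluster_assign, cellcycle, gsea,
#' trajectory, coexpr, and project in dependency order, writing each
#' stage's outputs plus a run manifest under \code{out_dir}. Any stage
#' failure halts the run with the stage named. All randomness derives from
#' \code{config$seed}; deterministic outputs are byte-identical across
#' runs with the same config.
#'
#' @param config a config list (see \code{\link{default_config}}).
#' @param out_dir output directory (created if needed).
#' @return the run manifest (also written as \code{manifest.json}),
#'   invisibly; the in-memory stage results are attached as attribute
#'   \code{results}.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile()) {
  check_config_keys(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  res <- list()
  step <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  res$sim <- step("simulate", {
    p <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
    ds <- simulate_hspc(p)
    write_matrix(ds$counts, file.path(out_dir, "counts.tsv"))
    write_annotation(ds$annotation, file.path(out_dir, "annotation.gtf"))
    write_gmt(ds$truth$gene_sets, file.path(out_dir, "truth_sets.gmt"))
    write_tf_scores(ds$atac, file.path(out_dir, "tf_scores.tsv"))
    write_tsv(ds$truth$cells, file.path(out_dir, "truth_cells.tsv"))
    ds
  })
  ds <- res$sim

  res$logm <- step("preprocess", {
    filtered <- qc_filter(ds$counts, config$qc$min_genes_detected,
                          config$qc$min_total)
    logm <- normalize_log(filtered)
    hvg <- select_hvg(logm, config$hvg$n_bins, config$hvg$z_cutoff,
                      c(config$hvg$mean_min, Inf))
    write_tsv(hvg$table, file.path(out_dir, "hvg.tsv"))
    write_matrix(round(logm, 6), file.path(out_dir, "logm.tsv"))
    attr(logm, "hvg") <- hvg$selected
    logm
  })
  logm <- res$logm
  hvg_sel <- attr(logm, "hvg")

  res$clust <- step("cluster_assign", {
    emb <- run_pca(scale_clip(logm[hvg_sel, , drop = FALSE]),
                   k = config$pca$k)
    cl <- dbscan_cluster(emb, eps = config$dbscan$eps,
                         min_pts = config$dbscan$min_pts,
                         n_pcs = config$dbscan$n_pcs)
    mk <- cluster_markers(logm, cl, config$markers$min_log_fc,
                          config$markers$q_max)
    universe <- rownames(logm)[rowSums(logm > 0) >= 3]
    asg <- assign_celltype(mk, ds$truth$gene_sets[ds$params$cluster_names],
                           universe, config$assign$q_max)
    write_tsv(data.frame(cell_id = names(cl$labels), cluster = cl$labels),
              file.path(out_dir, "clusters.tsv"))
    write_tsv(top_markers(mk, 10), file.path(out_dir, "markers_top10.tsv"))
    write_tsv(asg, file.path(out_dir, "assignment.tsv"))
    list(emb = emb, clusters = cl, markers = mk, assignment = asg)
  })

  res$phases <- step("cellcycle", {
    ph <- score_phase(logm, ds$truth$gene_sets$S_PHASE,
                      ds$truth$gene_sets$G2M_PHASE,
                      n_bins = config$cellcycle$n_bins,
                      bg_per_gene = config$cellcycle$bg_per_gene,
                      seed = derive_seed(config$seed, 11L))
    comp <- phase_composition(ph, attr(logm, "cell_meta")$compartment)
    write_tsv(data.frame(cell_id = names(ph$phase), phase = ph$phase,
                         ph$scores),
              file.path(out_dir, "phases.tsv"))
    write_tsv(comp, file.path(out_dir, "phase_composition.tsv"))
    ph
  })

  res$gsea <- step("gsea", {
    meta <- attr(logm, "cell_meta")
    cells <- colnames(logm)
    g <- gsea_significance(
      logm, cells[meta$compartment == "CD38pos"],
      cells[meta$compartment == "CD38neg"],
      ds$truth$gene_sets[c("CYCLING", "QUIESCENCE",
                           ds$params$cluster_names)],
      n_perm = config$gsea$n_perm, weight = config$gsea$weight,
      seed = derive_seed(config$seed, 12L))
    write_tsv(g, file.path(out_dir, "gsea.tsv"))
    g
  })

  res$traj <- step("trajectory", {
    demb <- diffusion_map(res$clust$emb,
                          k_neighbors = config$trajectory$k_neighbors,
                          n_comps = config$trajectory$n_comps)
    root <- select_root(logm, ds$truth$gene_sets[[
      ds$params$cluster_names[1]]])
    pt <- pseudotime(demb, root)
    cla <- absorb_noise(res$clust$clusters, res$clust$emb)
    graph <- connectivity_graph(demb$knn_edges, cla)
    br <- assign_branches(graph, cla, res$clust$assignment,
                          root_type = ds$params$cluster_names[1])
    dyn <- dynamic_genes(logm, pt, br$cell_branch,
                         q_threshold = config$trajectory$dynamic_q)
    write_tsv(data.frame(cell_id = names(pt$t), t = pt$t,
                         branch = br$cell_branch[names(pt$t)]),
              file.path(out_dir, "pseudotime.tsv"))
    write_tsv(br$tree, file.path(out_dir, "cluster_tree.tsv"))
    jsonlite::write_json(
      list(nodes = rownames(graph$weights), weights = graph$weights),
      file.path(out_dir, "connectivity.json"), matrix = "rowmajor")
    write_tsv(dyn[dyn$pattern != "flat", ],
              file.path(out_dir, "dynamic_genes.tsv"))
    list(demb = demb, pt = pt, graph = graph, branches = br, dyn = dyn)
  })

  res$coexpr <- step("coexpr", {
    bl <- res$traj$branches$cell_branch
    if (!config$coexpr$include_stem) bl[bl == "stem"] <- NA
    coll <- ds$truth$gene_sets[names(ds$params$coexpr_effect)]
    scan <- scan_collection(logm, coll, bl,
                            n_perm = config$coexpr$n_perm,
                            seed = derive_seed(config$seed, 13L),
                            min_expr_frac = config$coexpr$min_expr_frac)
    top <- scan$set[!scan$skipped][1]
    cv <- correlation_vectors(logm, coll[[top]], as_branch_list(bl),
                              config$coexpr$min_expr_frac)
    edges <- classify_edges(cv, config$coexpr$delta)
    write_tsv(scan, file.path(out_dir, "coexpr_scan.tsv"))
    write_tsv(edges, file.path(out_dir, "coexpr_edges.tsv"))
    list(scan = scan, edges = edges)
  })

  res$project <- step("project", {
    modules <- ds$truth$gene_sets[ds$params$cluster_names]
    pairs <- neighbor_pairs(ds$annotation, modules,
                            max_gap = config$project$max_gap)
    coding <- intersect(
      ds$annotation$gene_id[ds$annotation$biotype == "coding"],
      rownames(logm))
    memb <- run_pca(scale_clip(logm[coding, , drop = FALSE]),
                    k = config$pca$k)
    mrna <- project_modules(memb, modules, axes = 1:2,
                            q_threshold = config$project$q_threshold)
    lemb <- lncrna_pca(logm, ds$annotation, k = config$pca$k)
    lnc_modules <- split(pairs$lncRNA_id, pairs$module)
    lnc <- project_modules(lemb, lnc_modules, axes = 1:2,
                           q_threshold = config$project$q_threshold)
    tf_map <- lapply(modules, intersect, y = rownames(ds$atac))
    atac <- atac_project(ds$atac, tf_map,
                         q_threshold = config$project$q_threshold)
    write_tsv(pairs, file.path(out_dir, "neighbor_pairs.tsv"))
    write_tsv(mrna, file.path(out_dir, "projection_mrna.tsv"))
    write_tsv(lnc, file.path(out_dir, "projection_lncrna.tsv"))
    write_tsv(atac$projection, file.path(out_dir, "projection_atac.tsv"))
    list(pairs = pairs, mrna = mrna, lnc = lnc, atac = atac$projection)
  })

  manifest <- list(
    tool = "hspcflow",
    version = as.character(utils::packageVersion("hspcflow")),
    config_hash = fnv1a(config),
    seed = config$seed,
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "results") <- res
  invisible(manifest)
}
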