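#' Default pipeline configuration
#'
#' All analysis thresholds default to the reference study's values: 200
#' features / 15% mitochondrial / 3 cells for QC, 3000 HVGs and 30 PCs,
#' log-fold-change 0.25 for markers, top-100 DEG gene sets and top-50
#' staging panels, radius 75 for neighborhood statistics, permutation
#' p < 0.01, lineage FDR < 0.01, 10-spline smoothing, joint-cluster
#' resolution 2.25 with a strict >100 query-cell filter. The demo
#' configuration bundled with the package overrides the scale-dependent
#' values (cells, resolutions, retained-cluster minimum) to suit the small
#' synthetic dataset.
#'
#' @param out_dir artifact directory.
#' @param seed master seed; each stage derives its own from it.
#' @param ... overrides of any default.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("lungdyn_run_"), seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    sim = list(),
    qc = list(min_features = 200, max_mito_frac = 0.15, min_cells_per_gene = 3),
    transform = list(n_hvg = 3000, n_pcs = 30, target_sum = "median"),
    cluster = list(k_neighbors = 30, resolutions = c(0.3, 0.6, 1),
                   in_prop_threshold = 0.1),
    markers = list(logfc_min = 0.25, top_n = 100, stage_top_n = 50),
    composition = list(prior_sd = 2.5),
    trajectory = list(fdr = 0.01, spline_df = 10, n_modules = 2,
                      k_neighbors = 30, late_start = 17),
    spatial = list(radius = 75, radii = c(25, 50, 75, 100, 150),
                   n_perms = 200, proximal_z = 0),
    signaling = list(n_perms = 100, alpha = 0.01, hill_k = 0.5,
                     late_start = 18),
    benchmark = list(resolution = 2.25, min_query_cells = 100,
                     query_seed_offset = 1000)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Demo pipeline configuration
#'
#' A small synthetic-atlas run that exercises every stage in a few minutes
#' on one CPU. Scale-dependent parameters are reduced from the study
#' defaults; the planted structure is the generator's default.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(out_dir = tempfile("lungdyn_demo_"), seed = 1) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    sim = list(n_samples = 10, n_cells_per_sample = 250, n_genes = 400,
               markers_per_type = 8,
               trajectory_spec = list(paths = list(c("A", "B", "C"), c("A", "B", "D")),
                                      n_genes = 40, effect = 1.5)),
    qc = list(min_features = 50, max_mito_frac = 0.15, min_cells_per_gene = 3),
    transform = list(n_hvg = 400, n_pcs = 20, target_sum = "median"),
    spatial = list(radius = 75, radii = c(50, 75, 150), n_perms = 100,
                   proximal_z = 0),
    signaling = list(n_perms = 50, alpha = 0.02, hill_k = 0.5, late_start = 18),
    benchmark = list(resolution = 0.5, min_query_cells = 30,
                     query_seed_offset = 1000)
  )
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic atlas
#'
#' Executes simulate, QC, normalization/embedding, clustering + stability,
#' markers + scores, composition model selection, trajectory (pseudotime,
#' lineage genes, modules, vignette connectivity, fate probabilities),
#' spatial statistics, vignette-stratified signaling with spatial sender
#' restriction and information flow, and the organoid-style benchmarking
#' of a held-out synthetic query. Every stage writes CSV artifacts under
#' `cfg$out_dir` and a `manifest.json` records all parameters and seeds;
#' rerunning with the same configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()] (e.g. [demo_config()]).
#' @return list of in-memory stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = demo_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)

  # --- simulate ---------------------------------------------------------
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  atlas <- make_spatial(make_atlas(scfg))
  write_atlas(atlas, file.path(out_dir, "atlas"))
  res$atlas <- atlas

  # --- preprocess -------------------------------------------------------
  qc <- do.call(qc_filter, c(list(atlas$counts), cfg$qc))
  expr <- do.call(transform_expr, c(list(qc), cfg$transform))
  labelings <- lapply(cfg$cluster$resolutions, function(r)
    cluster_graph(expr$embedding, k_neighbors = cfg$cluster$k_neighbors,
                  resolution = r, seed = cfg$seed))
  stab <- resolution_stability(labelings, cfg$cluster$in_prop_threshold)
  pick <- which(cfg$cluster$resolutions == stab$recommended_resolution)
  if (!length(pick)) pick <- 1
  clusters <- labelings[[pick]]
  write_stage_csv(data.frame(cell_id = qc$cell_meta$cell_id,
                             cluster = clusters$labels),
                  out_dir, "clusters.csv")
  write_stage_csv(stab$edges, out_dir, "stability_edges.csv")
  res$expr <- expr; res$clusters <- clusters; res$stability <- stab

  # annotate clusters by the majority planted type (the synthetic stand-in
  # for manual annotation)
  maj <- tapply(qc$cell_meta$true_type, clusters$labels,
                function(t) names(sort(table(t), decreasing = TRUE))[1])
  anno <- as.character(maj[as.character(clusters$labels)])
  res$annotation <- anno

  # --- markers ----------------------------------------------------------
  mk <- rank_markers(expr, anno, logfc_min = cfg$markers$logfc_min)
  sets <- top_gene_sets(mk, cfg$markers$top_n)
  scores <- score_cells(expr, sets, normalize_by_own_type = anno,
                        seed = cfg$seed)
  write_stage_csv(mk, out_dir, "markers.csv")
  write_stage_csv(data.frame(cell_id = qc$cell_meta$cell_id,
                             as.data.frame(unclass(scores)),
                             check.names = FALSE),
                  out_dir, "scores.csv")
  res$markers <- mk; res$gene_sets <- sets; res$scores <- scores

  # --- composition ------------------------------------------------------
  meta <- qc$cell_meta
  comp_rows <- list()
  for (ty in sort(unique(anno))) {
    per <- aggregate(cbind(n_type = anno == ty) ~ sample_id + gestational_week,
                     data = cbind(meta, anno = anno), FUN = sum)
    tot <- as.numeric(table(meta$sample_id)[per$sample_id])
    cd <- composition_data(per$gestational_week, per$n_type, tot)
    sel <- select_model(cd, prior_sd = cfg$composition$prior_sd)
    raw <- c(coef(sel$fit), b1 = NA_real_, b2 = NA_real_)[c("b0", "b1", "b2")]
    comp_rows[[ty]] <- data.frame(type = ty, family = sel$best,
                                  t(sel$loo_scores), t(raw),
                                  stringsAsFactors = FALSE)
    res$composition[[ty]] <- sel
  }
  write_stage_csv(do.call(rbind, comp_rows), out_dir, "composition.csv")

  # --- trajectory -------------------------------------------------------
  paths <- scfg$trajectory_spec$paths
  root <- paths[[1]][1]
  traj_cells <- which(anno %in% unique(unlist(paths)))
  model <- infer_backbone(expr$embedding[traj_cells, , drop = FALSE],
                          anno[traj_cells], root)
  assoc <- association_test(expr$values[traj_cells, , drop = FALSE], model,
                            fdr = cfg$trajectory$fdr,
                            df = cfg$trajectory$spline_df)
  l1 <- names(assoc)[1]
  sel_genes <- assoc[[l1]]$selected
  mods <- if (length(sel_genes) >= 2) {
    idx <- lineage_cells(model, l1)
    gene_modules(expr$values[traj_cells, , drop = FALSE][idx, , drop = FALSE],
                 model$lineage_tau[idx, 1], sel_genes,
                 n_modules = cfg$trajectory$n_modules,
                 smooth_df = cfg$trajectory$spline_df)
  } else NULL
  vg <- vignette_connectivity(expr$embedding, anno, meta$gestational_week,
                              pseudotime_full(model, meta$cell_id, traj_cells),
                              k_neighbors = cfg$trajectory$k_neighbors,
                              late_start = cfg$trajectory$late_start)
  terminals <- vapply(paths, function(p) p[length(p)], "")
  fate <- fate_probabilities(expr$embedding[traj_cells, , drop = FALSE],
                             model$pseudotime, terminals, anno[traj_cells])
  write_stage_csv(data.frame(cell_id = meta$cell_id[traj_cells],
                             pseudotime = unname(model$pseudotime),
                             lineage = model$cell_lineage),
                  out_dir, "pseudotime.csv")
  write_stage_csv(do.call(rbind, lapply(names(assoc), function(l)
    data.frame(lineage = l, gene = assoc[[l]]$selected))),
    out_dir, "lineage_genes.csv")
  write_stage_csv(do.call(rbind, lapply(vg, function(v) v$edges)),
                  out_dir, "vignette_graph.csv")
  write_stage_csv(data.frame(cell_id = meta$cell_id[traj_cells],
                             as.data.frame(unclass(fate), check.names = FALSE)),
                  out_dir, "fate_probabilities.csv")
  res$trajectory <- model; res$association <- assoc; res$modules <- mods
  res$vignette_graph <- vg; res$fate <- fate

  # --- spatial ----------------------------------------------------------
  sp <- atlas$spatial
  focal <- scfg$lr_spec$receiver[1] %||% sort(unique(sp$type))[1]
  cooc <- cooccurrence_profile(sp, focal, cfg$spatial$radii)
  enr <- neighborhood_enrichment(sp, radius = cfg$spatial$radius,
                                 n_perms = cfg$spatial$n_perms,
                                 seed = cfg$seed)
  coloc <- weight_colocalization(atlas$spot_weights$weights)
  prox <- lapply(sort(unique(sp$type)), function(ty)
    proximal_types(enr, ty, threshold = cfg$spatial$proximal_z))
  names(prox) <- sort(unique(sp$type))
  write_stage_csv(data.frame(radius = rownames(cooc), cooc,
                             check.names = FALSE), out_dir, "cooccurrence.csv")
  write_stage_csv(data.frame(type = rownames(enr),
                             as.data.frame(unclass(enr), check.names = FALSE)),
                  out_dir, "enrichment_z.csv")
  write_stage_csv(data.frame(type = rownames(coloc$correlation),
                             coloc$correlation, check.names = FALSE),
                  out_dir, "weight_correlation.csv")
  res$cooccurrence <- cooc; res$enrichment <- enr; res$colocalization <- coloc
  res$proximal <- prox

  # --- signaling --------------------------------------------------------
  tabs <- vignette_interactions(expr, anno, meta$gestational_week,
                                scfg$lr_spec, n_perms = cfg$signaling$n_perms,
                                alpha = cfg$signaling$alpha, seed = cfg$seed,
                                hill_k = cfg$signaling$hill_k,
                                late_start = cfg$signaling$late_start)
  temp <- temporal_compare(expr, anno, meta$gestational_week, scfg$lr_spec,
                           sample_id = meta$sample_id,
                           restrict_senders = prox,
                           n_perms = cfg$signaling$n_perms,
                           alpha = cfg$signaling$alpha, seed = cfg$seed,
                           hill_k = cfg$signaling$hill_k,
                           late_start = cfg$signaling$late_start)
  flow <- information_flow(tabs)
  write_stage_csv(do.call(rbind, tabs), out_dir, "interactions.csv")
  write_stage_csv(temp, out_dir, "temporal_calls.csv")
  write_stage_csv(data.frame(pathway = rownames(flow$flow), flow$flow,
                             check.names = FALSE), out_dir, "information_flow.csv")
  res$interactions <- tabs; res$temporal <- temp; res$flow <- flow

  # --- benchmark --------------------------------------------------------
  qcfg <- scfg
  qcfg$seed <- cfg$seed + cfg$benchmark$query_seed_offset
  qcfg$n_samples <- max(2L, scfg$n_samples %/% 3L)
  query <- make_atlas(qcfg)$counts
  joint <- project_query(expr, query)
  jc <- joint_clusters(joint, resolution = cfg$benchmark$resolution,
                       min_query_cells = cfg$benchmark$min_query_cells,
                       seed = cfg$seed)
  ref_tau <- setNames(rep(NA_real_, nrow(expr$embedding)),
                      rownames(expr$embedding))
  ref_tau[names(model$pseudotime)] <- model$pseudotime
  pos <- position_clusters(jc, joint, ref_tau)
  qscores <- score_cells(project_scores_matrix(expr, query), res$gene_sets,
                         seed = cfg$seed)
  report <- benchmark_report(pos, jc, joint, scores = qscores)
  write_stage_csv(as.data.frame(report), out_dir, "benchmark_report.csv")
  res$benchmark <- report

  # --- manifest ---------------------------------------------------------
  manifest <- cfg
  class(manifest) <- NULL
  manifest$out_dir <- NULL  # volatile; the manifest lives in it
  manifest$stages <- list.files(out_dir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# Full-length pseudotime vector (NA off-trajectory) for vignette graphs.
pseudotime_full <- function(model, cell_ids, traj_idx) {
  tau <- rep(NA_real_, length(cell_ids))
  tau[traj_idx] <- model$pseudotime
  m <- mean(model$pseudotime)
  tau[is.na(tau)] <- m  # off-trajectory clusters sit at the mean for orientation
  tau
}

# Query log-normalized matrix in the reference normalization, for scoring.
project_scores_matrix <- function(reference, query) {
  lib <- Matrix::rowSums(query$counts)
  vals <- Matrix::Diagonal(x = reference$target_sum / lib) %*% query$counts
  vals@x <- log1p(vals@x)
  vals <- methods::as(vals, "CsparseMatrix")
  dimnames(vals) <- list(query$cell_meta$cell_id, query$gene_ids)
  vals
}
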