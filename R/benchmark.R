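#' Project a query dataset into the reference PCA space
#'
#' Normalizes the query with the reference normalization parameters (same
#' library-size target, log1p), applies the reference per-gene
#' centering/scaling and PCA loadings, and stacks the reference and query
#' coordinates. Genes are matched by identifier, never by position;
#' reference HVGs missing from the query are treated as zero after at
#' least half of them are present.
#'
#' @param reference a `lung_expr` from [transform_expr()] (carries
#'   loadings, centering and normalization parameters).
#' @param query a [count_matrix()].
#' @param min_overlap minimum fraction of reference HVGs the query must
#'   measure.
#' @return list(`embedding` stacked matrix, `origin` factor
#'   ("reference"/"query"), `query_embedding`).
#' @export
project_query <- function(reference, query, min_overlap = 0.5) {
  stopifnot(inherits(reference, "lung_expr"), inherits(query, "count_matrix"))
  hvg <- reference$hvg
  present <- hvg %in% query$gene_ids
  if (mean(present) < min_overlap)
    stop("insufficient gene overlap with reference HVGs (",
         round(100 * mean(present)), "%); missing: ",
         paste(head(hvg[!present], 10), collapse = ", "),
         if (sum(!present) > 10) " ..." else "")
  m <- query$counts
  lib <- Matrix::rowSums(m)
  if (any(lib == 0)) stop("query cells with zero counts")
  vals <- Matrix::Diagonal(x = reference$target_sum / lib) %*% m
  vals@x <- log1p(vals@x)
  X <- matrix(0, nrow(m), length(hvg),
              dimnames = list(query$cell_meta$cell_id, hvg))
  X[, hvg[present]] <- as.matrix(vals[, match(hvg[present], query$gene_ids),
                                      drop = FALSE])
  Xs <- sweep(sweep(X, 2, reference$center), 2, reference$scale, "/")
  cap <- reference$scale_max %||% 10
  Xs[Xs > cap] <- cap
  Xs[Xs < -cap] <- -cap
  qe <- Xs %*% reference$loadings
  emb <- rbind(reference$embedding, qe)
  origin <- factor(rep(c("reference", "query"),
                       c(nrow(reference$embedding), nrow(qe))),
                   levels = c("reference", "query"))
  list(embedding = emb, origin = origin, query_embedding = qe)
}

#' Joint clustering with a minimum-query-cell filter
#'
#' Clusters the stacked reference + query embedding and retains the
#' clusters containing strictly more than `min_query_cells` query cells.
#'
#' @param joint output of [project_query()].
#' @param resolution clustering resolution (the reference analysis uses
#'   2.25).
#' @param min_query_cells strict lower bound on query cells per retained
#'   cluster.
#' @param k_neighbors kNN size for the clustering graph.
#' @param seed integer seed.
#' @return list(`labels` (`cluster_labels` over all cells), `retained`
#'   cluster ids, `query_counts`).
#' @export
joint_clusters <- function(joint, resolution = 2.25, min_query_cells = 100,
                           k_neighbors = 30, seed = 0) {
  cl <- cluster_graph(joint$embedding, k_neighbors = k_neighbors,
                      resolution = resolution, seed = seed)
  qc <- table(factor(cl$labels[joint$origin == "query"],
                     levels = sort(unique(cl$labels))))
  retained <- as.integer(names(qc)[qc > min_query_cells])
  if (!length(retained)) warning("no clusters retained (> ", min_query_cells,
                                 " query cells)")
  list(labels = cl, retained = retained,
       query_counts = setNames(as.integer(qc), names(qc)))
}

#' Order retained joint clusters by average reference pseudotime
#'
#' Each retained cluster is assigned the mean pseudotime of the reference
#' cells it contains, then clusters are ordered ascending (ties broken by
#' cluster id). Retained clusters without reference cells are excluded
#' with a warning.
#'
#' @param clusters output of [joint_clusters()].
#' @param joint output of [project_query()].
#' @param reference_pseudotime named pseudotime vector over reference cells
#'   (names = cell ids matching the reference embedding rownames).
#' @return data.frame(cluster, n_query_cells, avg_pseudotime, position)
#'   sorted by position (0-based).
#' @export
position_clusters <- function(clusters, joint, reference_pseudotime) {
  labs <- clusters$labels$labels
  is_ref <- joint$origin == "reference"
  ref_ids <- rownames(joint$embedding)[is_ref]
  tau <- reference_pseudotime[ref_ids]
  out <- list()
  for (k in clusters$retained) {
    ref_in <- which(is_ref & labs == k)
    if (!length(ref_in) || all(is.na(tau[rownames(joint$embedding)[ref_in]]))) {
      warning("retained cluster ", k, " has no reference cells with ",
              "pseudotime; excluded")
      next
    }
    out[[length(out) + 1]] <- data.frame(
      cluster = k,
      n_query_cells = unname(clusters$query_counts[as.character(k)]),
      avg_pseudotime = mean(tau[rownames(joint$embedding)[ref_in]], na.rm = TRUE))
  }
  if (!length(out))
    return(data.frame(cluster = integer(), n_query_cells = integer(),
                      avg_pseudotime = numeric(), position = integer()))
  df <- do.call(rbind, out)
  df <- df[order(df$avg_pseudotime, df$cluster), ]
  df$position <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  df
}

#' Assemble the benchmarking report
#'
#' Joins the ordered cluster positions with per-cluster medians of the
#' normalized reference-type scores and the per-stage Spearman
#' correlations of the query clusters.
#'
#' @param positions output of [position_clusters()].
#' @param clusters output of [joint_clusters()].
#' @param joint output of [project_query()].
#' @param scores optional `score_matrix` over the query cells (columns =
#'   reference types).
#' @param staging optional `stage_cor` matrix whose rows are named by
#'   query cluster (as `cluster<k>`).
#' @return `benchmark_report` data.frame: one row per retained cluster
#'   with position, score medians (`score_<type>`), top-scoring type, and
#'   stage correlations (`stage_<w>`) with the best stage.
#' @export
benchmark_report <- function(positions, clusters, joint, scores = NULL,
                             staging = NULL) {
  df <- positions
  if (!nrow(df)) {
    out <- df
    class(out) <- c("benchmark_report", class(out))
    return(out)
  }
  labs <- clusters$labels$labels
  is_query <- joint$origin == "query"
  if (!is.null(scores)) {
    if (nrow(scores) != sum(is_query))
      stop("scores must cover the query cells")
    med <- matrix(NA_real_, nrow(df), ncol(scores),
                  dimnames = list(NULL, paste0("score_", colnames(scores))))
    for (i in seq_len(nrow(df))) {
      qin <- labs[is_query] == df$cluster[i]
      med[i, ] <- apply(scores[qin, , drop = FALSE], 2, median)
    }
    df <- cbind(df, med)
    df$top_type <- colnames(scores)[apply(med, 1, which.max)]
  }
  if (!is.null(staging)) {
    key <- paste0("cluster", df$cluster)
    miss <- setdiff(key, rownames(staging))
    if (length(miss)) stop("staging rows missing for ", paste(miss, collapse = ", "))
    sc <- staging[key, , drop = FALSE]
    colnames(sc) <- paste0("stage_", colnames(staging))
    df <- cbind(df, as.data.frame(sc))
    df$best_stage <- attr(staging, "best_stage")[match(key, rownames(staging))]
  }
  rownames(df) <- NULL
  class(df) <- c("benchmark_report", class(df))
  df
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", nrow(x), "retained query clusters\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}
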