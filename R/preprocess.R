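#' Construct a count matrix container
#'
#' Light container for raw counts plus per-cell metadata. Counts are stored
#' cells x genes (sparse); metadata must carry `cell_id` and `sample_id`,
#' and `gestational_week` (integer weeks in 10-19) when temporal analyses
#' are intended.
#'
#' @param counts cells x genes matrix of non-negative integers (coerced to
#'   sparse).
#' @param cell_meta data.frame aligned with the rows of `counts`.
#' @param gene_ids character vector aligned with the columns.
#' @param mito_prefix prefix identifying mitochondrial genes (default
#'   `"MT-"`).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta, gene_ids = colnames(counts),
                         mito_prefix = "MT-") {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (nrow(counts) != nrow(cell_meta)) stop("cell_meta rows must match cells")
  if (ncol(counts) != length(gene_ids)) stop("gene_ids must match genes")
  if (!all(c("cell_id", "sample_id") %in% names(cell_meta)))
    stop("cell_meta must contain cell_id and sample_id")
  gw <- cell_meta$gestational_week
  if (!is.null(gw) && any(!is.na(gw) & (gw < 10 | gw > 19)))
    stop("gestational_week must lie in 10-19")
  colnames(counts) <- gene_ids
  rownames(counts) <- cell_meta$cell_id
  out <- list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids,
              mito_flag = startsWith(gene_ids, mito_prefix))
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes (",
      sum(x$mito_flag), "mitochondrial )\n")
  invisible(x)
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells with fewer than `min_features` detected genes or a
#' mitochondrial count fraction above `max_mito_frac`, then removes genes
#' detected in fewer than `min_cells_per_gene` of the surviving cells. Cell
#' filters use the raw (pre-gene-filter) counts; the two passes are applied
#' once, cells first.
#'
#' @param raw a [count_matrix()].
#' @param min_features minimum detected genes per cell (cells with fewer are
#'   dropped; a cell with exactly `min_features` is kept).
#' @param max_mito_frac maximum mitochondrial count fraction (strictly
#'   greater is dropped).
#' @param min_cells_per_gene genes detected in fewer cells are dropped
#'   (exactly `min_cells_per_gene` is kept).
#' @return filtered `count_matrix`; the filter tallies are attached as
#'   attribute `qc_log`.
#' @export
qc_filter <- function(raw, min_features = 200, max_mito_frac = 0.15,
                      min_cells_per_gene = 3) {
  stopifnot(inherits(raw, "count_matrix"))
  m <- raw$counts
  detected <- Matrix::rowSums(m > 0)
  tot <- Matrix::rowSums(m)
  mito <- if (any(raw$mito_flag))
    Matrix::rowSums(m[, raw$mito_flag, drop = FALSE]) else rep(0, nrow(m))
  mito_frac <- ifelse(tot > 0, mito / tot, 0)
  keep_cell <- detected >= min_features & mito_frac <= max_mito_frac
  if (!any(keep_cell)) stop("empty after QC: all cells removed")
  m2 <- m[keep_cell, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(m2 > 0)
  keep_gene <- cells_per_gene >= min_cells_per_gene
  out <- count_matrix(m2[, keep_gene, drop = FALSE],
                      raw$cell_meta[keep_cell, , drop = FALSE],
                      raw$gene_ids[keep_gene])
  attr(out, "qc_log") <- c(cells_in = nrow(m), cells_removed = sum(!keep_cell),
                           genes_in = ncol(m), genes_removed = sum(!keep_gene))
  out
}

#' Normalize, select highly variable genes, and embed
#'
#' Library-size normalization to a common target (default: the median
#' library size), log(1 + x) transform, dispersion-based HVG selection
#' (variance/mean of the log values, z-scored within 20 equal-frequency
#' mean-expression bins), and PCA of the scaled HVGs. The returned loadings
#' and normalization parameters allow an external query to be projected into
#' the same space (see [project_query()]).
#'
#' @param qc QC-passed [count_matrix()].
#' @param n_hvg number of highly variable genes (clamped to the gene count
#'   with a warning).
#' @param n_pcs number of principal components.
#' @param target_sum `"median"` or a fixed count target.
#' @param scale_max cap on per-gene z-scores before PCA.
#' @return object of class `lung_expr`: log-normalized values (cells x
#'   genes, sparse), `hvg`, `embedding` (cells x n_pcs), `loadings`,
#'   per-gene `center`/`scale` used before PCA, `target_sum`, and the cell
#'   metadata carried through.
#' @export
transform_expr <- function(qc, n_hvg = 3000, n_pcs = 30, target_sum = "median",
                           scale_max = 10) {
  stopifnot(inherits(qc, "count_matrix"))
  m <- qc$counts
  lib <- Matrix::rowSums(m)
  if (any(lib == 0)) stop("cells with zero counts present; run qc_filter first")
  tgt <- if (identical(target_sum, "median")) median(lib) else as.numeric(target_sum)
  vals <- Matrix::Diagonal(x = tgt / lib) %*% m
  vals@x <- log1p(vals@x)
  vals <- methods::as(vals, "CsparseMatrix")
  dimnames(vals) <- dimnames(m)

  if (n_hvg > ncol(vals)) {
    warning("n_hvg exceeds gene count; clamped")
    n_hvg <- ncol(vals)
  }
  mu <- Matrix::colMeans(vals)
  ex2 <- Matrix::colMeans(vals^2)
  v <- (ex2 - mu^2) * nrow(vals) / max(1, nrow(vals) - 1)
  disp <- ifelse(mu > 0, v / mu, NA)
  usable <- which(!is.na(disp) & v > 0)
  nb <- max(1L, min(20L, length(usable) %/% 5L))
  bins <- if (nb < 2) rep(1L, length(usable)) else
    cut(rank(mu[usable], ties.method = "first"), breaks = nb, labels = FALSE)
  z <- rep(NA_real_, ncol(vals))
  for (b in seq_len(nb)) {
    ix <- usable[bins == b]
    if (length(ix) < 2) { z[ix] <- 0; next }
    md <- median(disp[ix])
    sdv <- stats::mad(disp[ix])
    if (sdv == 0) sdv <- sd(disp[ix])
    if (is.na(sdv) || sdv == 0) sdv <- 1
    z[ix] <- (disp[ix] - md) / sdv
  }
  hvg_ix <- usable[order(z[usable], decreasing = TRUE)][seq_len(min(n_hvg, length(usable)))]
  hvg <- qc$gene_ids[sort(hvg_ix)]

  X <- as.matrix(vals[, sort(hvg_ix), drop = FALSE])
  ctr <- colMeans(X)
  sdx <- apply(X, 2, sd)
  sdx[sdx == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, sdx, "/")
  Xs[Xs > scale_max] <- scale_max
  Xs[Xs < -scale_max] <- -scale_max
  n_pcs <- max(1L, min(n_pcs, ncol(Xs), nrow(Xs) - 1))
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  rownames(emb) <- qc$cell_meta$cell_id

  out <- list(values = vals, hvg = hvg, embedding = emb,
              loadings = pc$rotation, center = ctr, scale = sdx,
              scale_max = scale_max, target_sum = tgt,
              gene_ids = qc$gene_ids, cell_meta = qc$cell_meta,
              dispersion_z = z)
  class(out) <- "lung_expr"
  out
}

#' @export
print.lung_expr <- function(x, ...) {
  cat("lung_expr:", nrow(x$values), "cells x", ncol(x$values),
      "genes;", length(x$hvg), "HVGs;", ncol(x$embedding), "PCs\n")
  invisible(x)
}

#' Graph-based clustering of an embedding
#'
#' Builds a shared-nearest-neighbour graph (Jaccard overlap of kNN sets,
#' pruned below `prune`) and runs Louvain modularity optimization at the
#' requested resolution. Deterministic given `seed`. Labels are returned as
#' contiguous integers 0..K-1 ordered by decreasing cluster size.
#'
#' @param embedding cells x dims numeric matrix.
#' @param k_neighbors neighbours for the kNN graph (must be < cells).
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @param prune minimum Jaccard weight kept in the SNN graph.
#' @return object of class `cluster_labels`: list(labels, resolution, seed).
#' @export
cluster_graph <- function(embedding, k_neighbors = 30, resolution = 1, seed = 0,
                          prune = 1 / 15) {
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  n <- nrow(embedding)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  nn <- knn_index(embedding, k_neighbors)
  nn_sets <- cbind(seq_len(n), nn)  # include self for Jaccard as in Seurat
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn_sets)),
                              j = as.vector(nn_sets), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  k1 <- ncol(nn_sets)
  snn <- shared
  snn@x <- snn@x / (2 * k1 - snn@x)  # Jaccard
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  mem <- igraph::membership(comm)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(mem)])
  if (!is.null(rownames(embedding))) names(labels) <- rownames(embedding)
  out <- list(labels = labels, resolution = resolution, seed = seed)
  class(out) <- "cluster_labels"
  out
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat("cluster_labels:", length(x$labels), "cells,",
      length(unique(x$labels)), "clusters @ resolution", x$resolution, "\n")
  invisible(x)
}

#' Resolution-stability diagnostic across clusterings
#'
#' For each consecutive pair of resolutions, computes for every child
#' cluster the in-proportion of each parent: the fraction of the child's
#' cells contributed by that parent. A resolution is flagged as
#' over-clustered when any of its clusters draws an in-proportion of at
#' least `in_prop_threshold` from two or more parents. The report recommends
#' the largest unflagged resolution.
#'
#' @param labelings list of [cluster_graph()] outputs at increasing
#'   resolution, all covering the same cells.
#' @param in_prop_threshold minimum in-proportion for a parent edge to count.
#' @return object of class `stability_report`: `edges` (resolution pair,
#'   parent, child, in_proportion), `flagged_resolutions`,
#'   `recommended_resolution`, `threshold`.
#' @export
resolution_stability <- function(labelings, in_prop_threshold = 0.1) {
  if (length(labelings) < 2) stop("need labelings at >= 2 resolutions")
  labs <- lapply(labelings, function(l) l$labels)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 0L) != n))
    stop("labelings must cover the same cells")
  nms <- lapply(labs, names)
  if (!is.null(nms[[1]]) && any(vapply(nms, function(x) !identical(x, nms[[1]]), TRUE)))
    stop("labelings must cover the same cells")
  res <- vapply(labelings, function(l) l$resolution, 0)
  if (is.unsorted(res, strictly = TRUE)) stop("resolutions must be increasing")
  edges <- list()
  flagged <- logical(length(res))
  for (i in seq_len(length(labs) - 1)) {
    par <- labs[[i]]; chi <- labs[[i + 1]]
    tab <- table(par, chi)
    prop <- sweep(tab, 2, colSums(tab), "/")
    df <- as.data.frame(as.table(prop), stringsAsFactors = FALSE)
    names(df) <- c("parent", "child", "in_proportion")
    df <- df[df$in_proportion > 0, , drop = FALSE]
    df <- data.frame(parent_resolution = res[i], child_resolution = res[i + 1], df)
    edges[[i]] <- df
    multi <- tapply(df$in_proportion >= in_prop_threshold, df$child, sum)
    if (any(multi >= 2)) flagged[i + 1] <- TRUE
  }
  edges <- do.call(rbind, edges)
  unflagged <- res[!flagged]
  out <- list(edges = edges, flagged_resolutions = res[flagged],
              recommended_resolution = if (length(unflagged)) max(unflagged) else NA_real_,
              threshold = in_prop_threshold)
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report:", nrow(x$edges), "edges; flagged resolutions:",
      if (length(x$flagged_resolutions)) paste(x$flagged_resolutions, collapse = ", ")
      else "none",
      "; recommended:", x$recommended_resolution, "\n")
  invisible(x)
}
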