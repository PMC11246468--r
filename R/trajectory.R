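#' Infer a cluster-backbone trajectory and per-cell pseudotime
#'
#' Builds a minimum spanning tree over cluster centroids in the embedding
#' (Euclidean distances), takes every root-to-leaf path as a lineage, and
#' assigns each cell the arc-length position of its orthogonal projection
#' onto the piecewise-linear backbone of its nearest lineage. Lineage
#' weights are inverse-distance to each lineage's backbone, normalized per
#' cell.
#'
#' @param embedding cells x dims matrix (e.g. 30 PCs).
#' @param labels `cluster_labels` or per-cell labels.
#' @param root_cluster label of the root cluster.
#' @return object of class `trajectory_model`: `centroids`, `mst_edges`,
#'   `root`, `lineages` (list of ordered cluster paths), `pseudotime`
#'   (per cell), `lineage_weights` (cells x lineages), `cell_lineage`,
#'   `labels`.
#' @export
infer_backbone <- function(embedding, labels, root_cluster) {
  embedding <- as.matrix(embedding)
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  cl <- sort(unique(labs))
  if (length(cl) < 2) stop("need >= 2 clusters")
  if (!as.character(root_cluster) %in% cl)
    stop("root cluster ", root_cluster, " not found in labels")
  cent <- t(vapply(cl, function(k) colMeans(embedding[labs == k, , drop = FALSE]),
                   numeric(ncol(embedding))))
  rownames(cent) <- cl
  D <- as.matrix(dist(cent))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  deg <- igraph::degree(mst)
  root <- as.character(root_cluster)
  leaves <- setdiff(names(deg)[deg == 1], root)
  if (!length(leaves)) leaves <- setdiff(names(deg), root)
  lineages <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(mst, from = root, to = lf)$vpath[[1]]
    names(p)
  })
  names(lineages) <- vapply(lineages, function(p) p[length(p)], "")

  n <- nrow(embedding)
  L <- length(lineages)
  tau_l <- matrix(NA_real_, n, L)
  dist_l <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    path <- lineages[[l]]
    pts <- cent[path, , drop = FALSE]
    seg_len <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg_len))
    best_d <- rep(Inf, n); best_t <- rep(0, n)
    for (s in seq_len(nrow(pts) - 1)) {
      p0 <- pts[s, ]; dvec <- pts[s + 1, ] - p0
      len2 <- sum(dvec^2)
      tt <- if (len2 > 0)
        pmin(pmax((sweep(embedding, 2, p0) %*% dvec) / len2, 0), 1)
      else matrix(0, n, 1)
      proj <- sweep(tcrossprod(tt, dvec), 2, p0, "+")
      dd <- sqrt(rowSums((embedding - proj)^2))
      upd <- dd < best_d
      best_d[upd] <- dd[upd]
      best_t[upd] <- cum[s] + tt[upd] * seg_len[s]
    }
    tau_l[, l] <- best_t
    dist_l[, l] <- best_d
  }
  w <- 1 / (dist_l + 1e-8)
  w <- w / rowSums(w)
  colnames(w) <- names(lineages)
  best <- max.col(w, ties.method = "first")
  tau <- tau_l[cbind(seq_len(n), best)]
  names(tau) <- rownames(embedding)
  out <- list(centroids = cent,
              mst_edges = igraph::as_data_frame(mst, what = "edges")[, c("from", "to")],
              root = root, lineages = lineages, pseudotime = tau,
              lineage_weights = w, cell_lineage = names(lineages)[best],
              lineage_tau = tau_l, labels = labs)
  class(out) <- "trajectory_model"
  out
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("trajectory_model: root", x$root, "->",
      paste(names(x$lineages), collapse = ", "), "(",
      length(x$pseudotime), "cells )\n")
  for (l in names(x$lineages))
    cat("  lineage", l, ":", paste(x$lineages[[l]], collapse = " -> "), "\n")
  invisible(x)
}

# Cells considered to belong to a lineage: weight at least uniform, so
# trunk cells count in every plausible lineage (as in tradeSeq).
lineage_cells <- function(model, lineage) {
  L <- ncol(model$lineage_weights)
  which(model$lineage_weights[, lineage] >= 1 / L - 1e-12)
}

#' Lineage-gene association by spline regression
#'
#' For each lineage separately, regresses each gene's log-normalized
#' expression on a natural cubic spline basis of pseudotime (`df` basis
#' functions, knots at pseudotime quantiles) and tests against the
#' intercept-only model with an F-test. P-values are Benjamini-Hochberg
#' adjusted within each lineage; genes with adjusted p below `fdr` are the
#' lineage-associated set.
#'
#' @param expr `lung_expr` or cells x genes matrix.
#' @param model a [infer_backbone()] fit.
#' @param fdr adjusted-p threshold (applied per lineage).
#' @param df spline degrees of freedom.
#' @param genes optional subset of genes to test.
#' @param min_cells lineages with fewer cells are skipped with a warning.
#' @return list per lineage: `table` (gene, statistic, p_value, adj_p) and
#'   `selected` (genes passing `fdr`).
#' @export
association_test <- function(expr, model, fdr = 0.01, df = 10, genes = NULL,
                             min_cells = 30) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  if (is.null(genes)) genes <- colnames(vals)
  out <- list()
  for (l in names(model$lineages)) {
    idx <- lineage_cells(model, l)
    if (length(idx) < min_cells) {
      warning("lineage ", l, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    tau <- model$lineage_tau[idx, match(l, names(model$lineages))]
    Y <- as.matrix(vals[idx, genes, drop = FALSE])
    B <- splines::ns(tau, df = df)
    Xf <- cbind(1, B)
    fit <- lm.fit(Xf, Y)
    rss1 <- colSums(fit$residuals^2)
    rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
    df2 <- length(idx) - ncol(Xf)
    Fst <- ((rss0 - rss1) / df) / (rss1 / df2)
    p <- pf(Fst, df, df2, lower.tail = FALSE)
    p[!is.finite(Fst) | rss0 <= 0] <- 1
    adj <- p.adjust(p, "BH")
    tab <- data.frame(gene = genes, statistic = Fst, p_value = p, adj_p = adj,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$adj_p, tab$p_value), ]
    out[[l]] <- list(table = tab, selected = tab$gene[tab$adj_p < fdr])
  }
  out
}

#' Trajectory gene modules and smoothed heatmap matrix
#'
#' Genes are clustered by Ward linkage on 1 minus the Pearson correlation
#' matrix of their expression over cells ordered by pseudotime; the tree is
#' cut at `n_modules`. Heatmap rows are spline-smoothed (natural cubic,
#' `smooth_df` basis functions) fitted values over a pseudotime grid.
#'
#' @param expr `lung_expr` or cells x genes matrix.
#' @param tau per-cell pseudotime (aligned with rows of `expr`).
#' @param genes genes to include (>= 2).
#' @param n_modules number of modules to cut the dendrogram into.
#' @param smooth_df spline degrees of freedom for smoothing.
#' @param grid_n grid points along pseudotime.
#' @return list(`modules` named integer vector, `smoothed` genes x grid
#'   matrix, `grid`, `hclust`).
#' @export
gene_modules <- function(expr, tau, genes, n_modules = 2, smooth_df = 10,
                         grid_n = 100) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  if (length(genes) < 2) stop("need >= 2 genes")
  ord <- order(tau)
  Y <- as.matrix(vals[ord, genes, drop = FALSE])
  vv <- apply(Y, 2, var)
  if (any(vv == 0)) {
    warning("constant genes removed: ", paste(genes[vv == 0], collapse = ", "))
    Y <- Y[, vv > 0, drop = FALSE]
    genes <- colnames(Y)
    if (length(genes) < 2) stop("need >= 2 non-constant genes")
  }
  D <- 1 - cor(Y)
  hc <- hclust(as.dist(D), method = "ward.D2")
  modules <- cutree(hc, k = min(n_modules, length(genes)))
  tt <- sort(tau)
  df_use <- min(smooth_df, length(unique(tt)) - 1)
  B <- splines::ns(tt, df = df_use)
  grid <- seq(min(tau), max(tau), length.out = grid_n)
  Bg <- splines::ns(grid, df = df_use,
                    knots = attr(B, "knots"),
                    Boundary.knots = attr(B, "Boundary.knots"))
  fit <- lm.fit(cbind(1, B), Y)
  smoothed <- t(cbind(1, Bg) %*% fit$coefficients)
  rownames(smoothed) <- genes
  list(modules = modules, smoothed = smoothed, grid = grid, hclust = hc)
}

#' Vignette-stratified cluster-graph connectivity
#'
#' Splits cells into developmental vignettes by gestational week, builds a
#' kNN graph within each vignette, and scores each cluster pair by observed
#' inter-cluster edges over the count expected under random edge placement
#' given cluster sizes, capped at 1. Edges are oriented from the cluster
#' with lower mean pseudotime to the higher.
#'
#' @param embedding cells x dims matrix.
#' @param labels `cluster_labels` or per-cell labels.
#' @param gestational_week per-cell integer weeks.
#' @param pseudotime per-cell pseudotime.
#' @param k_neighbors kNN size.
#' @param late_start first week of the late vignette (17 by default; the
#'   signaling convention uses 18, leaving GW17 unassigned).
#' @return object of class `vignette_graph`: per vignette a list with
#'   `connectivity` (symmetric matrix, zero diagonal) and `edges`
#'   (data.frame vignette, from, to, connectivity) oriented by pseudotime.
#' @export
vignette_connectivity <- function(embedding, labels, gestational_week,
                                  pseudotime, k_neighbors = 30,
                                  late_start = 17) {
  embedding <- as.matrix(embedding)
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  if (any(is.na(gestational_week))) stop("every cell needs a gestational week")
  vig <- gw_vignette(gestational_week, late_start = late_start)
  out <- list()
  for (v in c("early", "mid", "late")) {
    idx <- which(!is.na(vig) & vig == v)
    if (length(idx) == 0) { out[[v]] <- NULL; next }
    sub_labs <- labs[idx]
    cl <- sort(unique(sub_labs))
    if (length(cl) < 2) {
      warning("vignette ", v, " has fewer than 2 clusters; empty graph")
      out[[v]] <- list(connectivity = matrix(0, 0, 0),
                       edges = data.frame())
      next
    }
    k_use <- min(k_neighbors, length(idx) - 1)
    nn <- knn_index(embedding[idx, , drop = FALSE], k_use)
    ed <- knn_edges(nn)
    conn <- connectivity_from_edges(ed, sub_labs, cl)
    mt <- tapply(pseudotime[idx], sub_labs, mean)
    edges <- list()
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (a >= b || conn[a, b] <= 0) next
      lo <- if (mt[cl[a]] <= mt[cl[b]]) cl[a] else cl[b]
      hi <- setdiff(c(cl[a], cl[b]), lo)
      edges[[length(edges) + 1]] <- data.frame(
        vignette = v, from = lo, to = hi, connectivity = conn[a, b],
        stringsAsFactors = FALSE)
    }
    out[[v]] <- list(connectivity = conn,
                     edges = if (length(edges)) do.call(rbind, edges)
                             else data.frame())
  }
  class(out) <- "vignette_graph"
  out
}

# PAGA-style observed/expected ratio of inter-cluster edges, capped at 1.
connectivity_from_edges <- function(edges, labs, cl) {
  K <- length(cl)
  conn <- matrix(0, K, K, dimnames = list(cl, cl))
  if (!nrow(edges)) return(conn)
  m <- nrow(edges)
  n <- length(labs)
  sizes <- as.numeric(table(factor(labs, levels = cl)))
  names(sizes) <- cl
  la <- labs[edges[, 1]]; lb <- labs[edges[, 2]]
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a >= b) next
    obs <- sum((la == cl[a] & lb == cl[b]) | (la == cl[b] & lb == cl[a]))
    expct <- m * (sizes[a] * sizes[b]) / (n * (n - 1) / 2)
    conn[a, b] <- conn[b, a] <- min(1, if (expct > 0) obs / expct else 0)
  }
  conn
}

#' Fate probabilities from a pseudotime-directed absorbing Markov chain
#'
#' Builds a kNN transition graph whose edge weights downweight moves to
#' lower pseudotime through a logistic function of the pseudotime
#' difference, makes the cells of the terminal clusters absorbing, and
#' solves the absorption probabilities exactly as a sparse linear system.
#'
#' @param embedding cells x dims matrix.
#' @param pseudotime per-cell pseudotime (finite).
#' @param terminal_clusters labels of the absorbing clusters.
#' @param labels `cluster_labels` or per-cell labels.
#' @param k_neighbors kNN size.
#' @param kernel_scale logistic scale for the pseudotime difference;
#'   default the SD of the difference over kNN edges.
#' @return `fate_matrix`: cells x terminal-states matrix of absorption
#'   probabilities (rows sum to 1).
#' @export
fate_probabilities <- function(embedding, pseudotime, terminal_clusters,
                               labels, k_neighbors = 15, kernel_scale = NULL) {
  embedding <- as.matrix(embedding)
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  terminal_clusters <- as.character(terminal_clusters)
  if (!length(terminal_clusters) || !any(labs %in% terminal_clusters))
    stop("no cells in terminal clusters")
  n <- nrow(embedding)
  nn <- knn_index(embedding, min(k_neighbors, n - 1))
  from <- rep(seq_len(n), ncol(nn))
  to <- as.vector(nn)
  dtau <- pseudotime[to] - pseudotime[from]
  if (is.null(kernel_scale)) kernel_scale <- sd(dtau)
  if (!is.finite(kernel_scale) || kernel_scale <= 0) kernel_scale <- 1
  wt <- invlogit(dtau / kernel_scale)

  absorbing <- labs %in% terminal_clusters
  # drop outgoing edges of absorbing cells
  keep <- !absorbing[from]
  from <- from[keep]; to <- to[keep]; wt <- wt[keep]
  rs <- tapply(wt, from, sum)
  no_out <- setdiff(which(!absorbing), as.integer(names(rs)[rs > 0]))
  if (length(no_out)) {
    warning(length(no_out), " cells without outgoing weight; linked to ",
            "nearest terminal cell")
    term_idx <- which(absorbing)
    for (i in no_out) {
      d <- colSums((t(embedding[term_idx, , drop = FALSE]) - embedding[i, ])^2)
      from <- c(from, i); to <- c(to, term_idx[which.min(d)]); wt <- c(wt, 1)
    }
  }
  P <- Matrix::sparseMatrix(i = from, j = to, x = wt, dims = c(n, n))
  rs <- Matrix::rowSums(P)
  trans <- which(!absorbing)
  P[trans, ] <- Matrix::Diagonal(x = 1 / rs[trans]) %*% P[trans, , drop = FALSE]

  states <- terminal_clusters[terminal_clusters %in% unique(labs[absorbing])]
  A <- which(absorbing)
  Q <- P[trans, trans, drop = FALSE]
  Rm <- P[trans, A, drop = FALSE]
  ind <- Matrix::sparseMatrix(i = seq_along(A),
                              j = match(labs[A], states),
                              x = 1, dims = c(length(A), length(states)))
  IQ <- Matrix::Diagonal(length(trans)) - Q
  B <- tryCatch(Matrix::solve(IQ, Rm %*% ind),
                error = function(e) stop("singular absorption system: ",
                                         conditionMessage(e)))
  out <- matrix(0, n, length(states),
                dimnames = list(rownames(embedding), states))
  out[trans, ] <- as.matrix(B)
  out[cbind(A, match(labs[A], states))] <- 1
  class(out) <- c("fate_matrix", class(out))
  out
}
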