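#' Two-sample Wilcoxon rank-sum test for a vector of observations
#'
#' Exact p-values (via the exact rank-sum null distribution) when both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Matches the convention of base R's two-sided test.
#'
#' @param x numeric values.
#' @param in_group logical, group membership.
#' @param exact_max largest group size for which the exact distribution is
#'   used.
#' @return list(statistic = U for the in-group, p_value).
#' @keywords internal
wilcox_rank_sum <- function(x, in_group, exact_max = 50) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  r <- rank(x)
  U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- if (U > n1 * n2 / 2)
      pwilcox(U - 1, n1, n2, lower.tail = FALSE) else pwilcox(U, n1, n2)
    p <- min(2 * p, 1)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
    d <- U - mu
    cc <- sign(d) * 0.5
    z <- if (sigma > 0) (d - cc) / sigma else 0
    p <- min(2 * pnorm(-abs(z)), 1)
  }
  list(statistic = U, p_value = p)
}

#' Rank one-vs-rest marker genes per cluster
#'
#' One-vs-rest two-sided Wilcoxon rank-sum tests per gene per cluster on
#' log-normalized expression. The log fold change is
#' `ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`. Genes failing
#' `log_fc > logfc_min` (and, when `positive_only`, positivity) are dropped
#' before Benjamini-Hochberg adjustment, which is applied within each
#' cluster.
#'
#' @param expr a `lung_expr` (or any cells x genes log-normalized matrix).
#' @param labels a `cluster_labels` or vector of per-cell labels.
#' @param logfc_min retain genes with log fold change strictly above this.
#' @param positive_only drop genes not elevated in the cluster.
#' @param min_cluster_size clusters smaller than this are skipped with a
#'   warning.
#' @return `marker_table`: data.frame(cluster, gene, log_fc, p_value, adj_p,
#'   pct_in, pct_out), ordered by cluster then adj_p then decreasing
#'   log_fc.
#' @export
rank_markers <- function(expr, labels, logfc_min = 0.25, positive_only = TRUE,
                         min_cluster_size = 3) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.vector(labs)
  if (length(labs) != nrow(vals)) stop("labels must match cells")
  cl <- sort(unique(labs))
  if (length(cl) < 2) stop("need >= 2 clusters")
  out <- list()
  for (k in cl) {
    ing <- labs == k
    if (sum(ing) < min_cluster_size) {
      warning("cluster ", k, " has fewer than ", min_cluster_size,
              " cells; skipped")
      next
    }
    m_in <- Matrix::colMeans(expm1_sparse(vals[ing, , drop = FALSE]))
    m_out <- Matrix::colMeans(expm1_sparse(vals[!ing, , drop = FALSE]))
    log_fc <- log((m_in + 1) / (m_out + 1))
    keep <- log_fc > logfc_min
    if (positive_only) keep <- keep & (log_fc > 0)
    idx <- which(keep)
    if (!length(idx)) next
    pv <- vapply(idx, function(j) {
      wilcox_rank_sum(as.numeric(vals[, j]), ing)$p_value
    }, 0)
    pct_in <- Matrix::colMeans(vals[ing, idx, drop = FALSE] > 0)
    pct_out <- Matrix::colMeans(vals[!ing, idx, drop = FALSE] > 0)
    df <- data.frame(cluster = k, gene = colnames(vals)[idx],
                     log_fc = log_fc[idx], p_value = pv,
                     adj_p = p.adjust(pv, "BH"),
                     pct_in = as.numeric(pct_in), pct_out = as.numeric(pct_out),
                     stringsAsFactors = FALSE)
    out[[as.character(k)]] <- df[order(df$adj_p, -df$log_fc), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", class(res))
  res
}

expm1_sparse <- function(m) {
  if (inherits(m, "sparseMatrix")) { m@x <- expm1(m@x); m } else expm1(m)
}

#' Extract ranked top-n gene sets from a marker table
#'
#' @param markers a [rank_markers()] table.
#' @param n genes per cluster (default the top 100 used for cell-type
#'   scores).
#' @return named list of character vectors, ranked by adj_p then log fold
#'   change.
#' @export
top_gene_sets <- function(markers, n = 100) {
  sp <- split(markers, markers$cluster)
  lapply(sp, function(df) head(df$gene, n))
}

#' Score cells against gene sets with expression-matched controls
#'
#' For each gene set, the score of a cell is the mean log-normalized
#' expression of the set genes minus the mean over a control set sampled
#' (seeded) from expression-matched bins of the background pool. The pool
#' is all genes expressed in more than `min_cells_in_pool` cells, excluding
#' the set genes. With `normalize_by_own_type`, each set's column is divided
#' by the median score of the cells of the matching type, so that the
#' median own-type score is exactly 1.
#'
#' @param expr a `lung_expr` or cells x genes log-normalized matrix.
#' @param gene_sets a named list of gene vectors (or a single character
#'   vector).
#' @param min_cells_in_pool pool keeps genes expressed in strictly more
#'   cells than this.
#' @param n_bins expression bins for control matching.
#' @param ctrl_per_gene control genes sampled per set gene.
#' @param normalize_by_own_type optional per-cell type labels named as the
#'   sets; `NULL` for raw scores.
#' @param seed integer seed for control sampling.
#' @return `score_matrix`: cells x sets numeric matrix with attribute
#'   `normalized`.
#' @export
score_cells <- function(expr, gene_sets, min_cells_in_pool = 10, n_bins = 25,
                        ctrl_per_gene = 50, normalize_by_own_type = NULL,
                        seed = 0) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  universe <- colnames(vals)
  n_expressing <- Matrix::colSums(vals > 0)
  avg <- Matrix::colMeans(vals)
  pool_all <- universe[n_expressing > min_cells_in_pool]
  scores <- matrix(NA_real_, nrow(vals), length(gene_sets),
                   dimnames = list(rownames(vals), names(gene_sets)))
  with_seed(seed, {
    for (s in seq_along(gene_sets)) {
      gs <- gene_sets[[s]]
      missing <- setdiff(gs, universe)
      if (length(missing)) {
        warning("genes missing from matrix dropped: ",
                paste(missing, collapse = ", "))
        gs <- intersect(gs, universe)
      }
      if (!length(gs)) stop("gene set ", names(gene_sets)[s], " empty after drops")
      pool <- setdiff(pool_all, gs)
      if (length(pool) < length(gs))
        stop("background pool smaller than gene set after exclusions")
      ranked <- union(pool, gs)
      bins <- cut(rank(avg[ranked], ties.method = "first"),
                  breaks = n_bins, labels = FALSE)
      names(bins) <- ranked
      ctrl <- character()
      for (g in gs) {
        cand <- pool[bins[pool] == bins[g]]
        if (!length(cand)) cand <- pool
        ctrl <- c(ctrl, sample(cand, min(ctrl_per_gene, length(cand))))
      }
      ctrl <- unique(ctrl)
      scores[, s] <- Matrix::rowMeans(vals[, gs, drop = FALSE]) -
        Matrix::rowMeans(vals[, ctrl, drop = FALSE])
    }
  })
  normalized <- FALSE
  if (!is.null(normalize_by_own_type)) {
    labs <- normalize_by_own_type
    for (s in colnames(scores)) {
      own <- which(labs == s)
      if (length(own)) {
        md <- median(scores[own, s])
        if (md != 0) scores[, s] <- scores[, s] / md
      }
    }
    normalized <- TRUE
  }
  attr(scores, "normalized") <- normalized
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' Overlap coefficient between two gene sets
#'
#' The number of shared genes divided by the size of the smaller set.
#'
#' @param set_a,set_b non-empty character vectors.
#' @return fraction in \[0, 1\].
#' @export
overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) stop("gene sets must be non-empty")
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Spearman staging of query profiles against reference stages
#'
#' Builds a panel as the union of the top-`k` stage-discriminating genes
#' over all stages and computes Spearman correlations between each query
#' group profile and each reference stage profile over the panel. The
#' best stage per query maximizes the correlation; ties break toward the
#' lower stage index.
#'
#' @param query_profiles genes x query-groups matrix of mean log expression
#'   (rownames = genes).
#' @param reference_stages genes x stages matrix of mean log expression.
#' @param stage_degs list (per stage) of ranked stage-vs-rest marker genes.
#' @param k top genes kept per stage (all if fewer available).
#' @return `stage_cor`: query x stage Spearman matrix with attributes
#'   `panel` and `best_stage`.
#' @export
stage_correlation <- function(query_profiles, reference_stages, stage_degs,
                              k = 50) {
  query_profiles <- as.matrix(query_profiles)
  reference_stages <- as.matrix(reference_stages)
  panel <- unique(unlist(lapply(stage_degs, head, k)))
  panel <- Reduce(intersect, list(panel, rownames(query_profiles),
                                  rownames(reference_stages)))
  if (length(panel) < 3) stop("fewer than 3 panel genes shared across inputs")
  rho <- cor(query_profiles[panel, , drop = FALSE],
             reference_stages[panel, , drop = FALSE], method = "spearman")
  best <- apply(rho, 1, which.max)  # which.max takes the first (lowest) on ties
  structure(rho, class = c("stage_cor", class(rho)), panel = panel,
            best_stage = colnames(reference_stages)[best])
}

#' Per-stage mean profiles and stage-discriminating genes
#'
#' Convenience wrapper: computes per-gestational-week mean log-expression
#' profiles and one-stage-vs-rest markers via [rank_markers()].
#'
#' @param expr a `lung_expr`.
#' @param stages per-cell stage labels (e.g. gestational week).
#' @param logfc_min marker log-fold-change threshold.
#' @return list(profiles = genes x stages matrix, degs = ranked gene lists
#'   per stage).
#' @export
stage_profiles <- function(expr, stages, logfc_min = 0.25) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  st <- sort(unique(stages))
  prof <- vapply(st, function(s)
    Matrix::colMeans(vals[stages == s, , drop = FALSE]), numeric(ncol(vals)))
  colnames(prof) <- as.character(st)
  rownames(prof) <- colnames(vals)
  mk <- rank_markers(vals, as.character(stages), logfc_min = logfc_min)
  degs <- top_gene_sets(mk, n = Inf)
  degs <- degs[as.character(st)[as.character(st) %in% names(degs)]]
  list(profiles = prof, degs = degs)
}
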