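#' @importFrom stats median sd mad var cor rnorm runif rbinom rnbinom
#'   rmultinom dbinom pf p.adjust pnorm pwilcox dist hclust cutree as.dist
#'   prcomp lm.fit wilcox.test setNames aggregate predict coef residuals
#'   simulate
#' @importFrom utils head combn
#' @importFrom methods as
NULL

invlogit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Brute-force k-nearest-neighbour indices
#'
#' Exact Euclidean kNN computed blockwise; adequate at the cell numbers this
#' package targets (tens of thousands).
#'
#' @param x numeric matrix (rows = points).
#' @param k number of neighbours (self excluded).
#' @param block rows per block.
#' @return integer matrix, rows = points, columns = the k nearest neighbours.
#' @keywords internal
knn_index <- function(x, k, block = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k_neighbors must be smaller than the number of cells")
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (ii in seq_along(idx)) {
      d2[ii, idx[ii]] <- Inf
      ord <- order(d2[ii, ])[seq_len(k)]
      out[idx[ii], ] <- ord
    }
  }
  out
}

# Undirected edge list (i < j) of the kNN graph given an index matrix.
knn_edges <- function(nn) {
  n <- nrow(nn)
  from <- rep(seq_len(n), ncol(nn))
  to <- as.vector(nn)
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(a + b * (n + 1))
  cbind(a[keep], b[keep])
}

# Pairs (i, j), i != j, within Euclidean distance <= r (closed ball).
radius_edges <- function(xy, r, block = 2048L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  sq <- rowSums(xy^2)
  res_i <- list(); res_j <- list(); kk <- 0L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xy[idx, , drop = FALSE], xy)
    hit <- which(d2 <= r^2 + 1e-12, arr.ind = TRUE)
    i <- idx[hit[, 1]]; j <- hit[, 2]
    keep <- i < j
    kk <- kk + 1L
    res_i[[kk]] <- i[keep]; res_j[[kk]] <- j[keep]
  }
  cbind(unlist(res_i), unlist(res_j))
}

geom_mean <- function(x) exp(mean(log(pmax(x, .Machine$double.eps))))

# Seeded RNG scope: evaluates expr with a local seed, restoring global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
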