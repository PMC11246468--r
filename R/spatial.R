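#' Spatial co-occurrence profile around a focal cell type
#'
#' For each radius, pools every non-focal cell lying within Euclidean
#' distance of at most that radius of any focal cell, and reports the
#' proportion of each cell type in the pool. A radius whose pool is empty
#' yields `NA` proportions (undefined, not zero).
#'
#' @param map data.frame with columns cell_id, x, y, type.
#' @param focal_type the focal type (must be present).
#' @param radii positive radii in the map's coordinate units.
#' @return matrix radii x types of proportions (rows sum to 1 where the
#'   pool is non-empty).
#' @export
cooccurrence_profile <- function(map, focal_type, radii = c(25, 50, 75, 100, 150)) {
  stopifnot(all(c("x", "y", "type") %in% names(map)))
  if (any(radii <= 0)) stop("radii must be > 0")
  focal <- which(map$type == focal_type)
  if (!length(focal)) stop("no cells of focal type ", focal_type)
  other <- which(map$type != focal_type)
  types <- sort(unique(map$type))
  types_out <- setdiff(types, focal_type)
  out <- matrix(NA_real_, length(radii), length(types_out),
                dimnames = list(as.character(radii), types_out))
  if (!length(other)) return(out)
  fx <- as.matrix(map[focal, c("x", "y")])
  ox <- as.matrix(map[other, c("x", "y")])
  # min distance from each non-focal cell to any focal cell (blockwise)
  mind <- rep(Inf, length(other))
  for (start in seq(1, length(other), by = 2048)) {
    ix <- start:min(start + 2047, length(other))
    d2 <- outer(rowSums(ox[ix, , drop = FALSE]^2), rowSums(fx^2), "+") -
      2 * tcrossprod(ox[ix, , drop = FALSE], fx)
    mind[ix] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  for (r in seq_along(radii)) {
    pool <- map$type[other[mind <= radii[r] + 1e-12]]
    if (!length(pool)) next
    tab <- table(factor(pool, levels = types_out))
    out[r, ] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Neighborhood enrichment z-scores by label permutation
#'
#' Builds the radius neighbour graph (closed ball), counts edges between
#' every pair of cell types, and compares each observed count with its
#' null distribution under `n_perms` seeded permutations of the type
#' labels: `z = (observed - mean(null)) / sd(null)`.
#'
#' @param map data.frame with columns x, y, type.
#' @param radius neighbourhood radius (default 75 units).
#' @param n_perms label permutations.
#' @param seed integer seed.
#' @return symmetric type x type z-score matrix (attribute `observed`
#'   carries the observed edge counts). Pairs with zero null SD get z = 0
#'   with a warning.
#' @export
neighborhood_enrichment <- function(map, radius = 75, n_perms = 1000, seed = 0) {
  stopifnot(all(c("x", "y", "type") %in% names(map)))
  if (radius <= 0) stop("radius must be > 0")
  types <- sort(unique(map$type))
  K <- length(types)
  if (K < 2) stop("need >= 2 cell types")
  ed <- radius_edges(as.matrix(map[, c("x", "y")]), radius)
  lab <- match(map$type, types)
  npair <- K * (K + 1) / 2
  pair_index <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1) * K - (lo - 1) * (lo - 2) / 2 + hi - lo + 1
  }
  count_pairs <- function(l) {
    if (!nrow(ed)) return(numeric(npair))
    tabulate(pair_index(l[ed[, 1]], l[ed[, 2]]), nbins = npair)
  }
  obs <- count_pairs(lab)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_perms), function(i) count_pairs(sample(lab)),
           numeric(npair))
  })
  mu <- rowMeans(null_mat)
  sg <- apply(null_mat, 1, sd)
  z <- ifelse(sg > 0, (obs - mu) / sg, 0)
  if (any(sg == 0)) warning("pairs with zero null SD reported as z = 0")
  zm <- matrix(0, K, K, dimnames = list(types, types))
  om <- matrix(0, K, K, dimnames = list(types, types))
  idx <- 1
  for (a in seq_len(K)) for (b in a:K) {
    zm[a, b] <- zm[b, a] <- z[idx]
    om[a, b] <- om[b, a] <- obs[idx]
    idx <- idx + 1
  }
  attr(zm, "observed") <- om
  zm
}

#' Colocalization of deconvolution weights across spots
#'
#' Pearson correlation of per-type weight columns across spots, plus an
#' average-linkage dendrogram on 1 minus the correlation giving a display
#' order of frequently colocalized types.
#'
#' @param weights spots x types matrix; rows must sum to 1 (within 1e-6).
#' @return list(`correlation` symmetric matrix, `order` type order,
#'   `hclust`). Zero-variance columns are excluded with a warning.
#' @export
weight_colocalization <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 3) stop("need >= 3 spots")
  if (ncol(weights) < 2) stop("need >= 2 types")
  if (any(abs(rowSums(weights) - 1) > 1e-6))
    stop("weight rows must sum to 1")
  vv <- apply(weights, 2, var)
  if (any(vv == 0)) {
    warning("zero-variance weight columns excluded: ",
            paste(colnames(weights)[vv == 0], collapse = ", "))
    weights <- weights[, vv > 0, drop = FALSE]
    if (ncol(weights) < 2) stop("fewer than 2 variable types")
  }
  cc <- cor(weights)
  hc <- hclust(as.dist(1 - cc), method = "average")
  list(correlation = cc, order = colnames(weights)[hc$order], hclust = hc)
}

#' Spatially close cell types around a focal type
#'
#' Thresholds a neighborhood-enrichment row (or a co-occurrence profile
#' row at a reference radius) to define the set of types considered
#' spatially close to the focal type — the criterion used to restrict
#' ligand senders.
#'
#' @param stat either a z-score matrix from [neighborhood_enrichment()] or
#'   a co-occurrence matrix from [cooccurrence_profile()].
#' @param focal_type focal type (row of the statistic for enrichment;
#'   ignored for co-occurrence output, which is already focal).
#' @param threshold minimum statistic value (default z > 0).
#' @param radius for co-occurrence output, the row (radius) to threshold.
#' @return character vector of types, excluding the focal type.
#' @export
proximal_types <- function(stat, focal_type, threshold = 0, radius = NULL) {
  if (!is.null(radius)) {
    row <- stat[as.character(radius), ]
  } else {
    if (!focal_type %in% rownames(stat))
      stop("focal type ", focal_type, " absent from the statistic")
    row <- stat[focal_type, ]
  }
  row <- row[!is.na(row)]
  sort(setdiff(names(row)[row > threshold], focal_type))
}
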