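# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic atlas (seed 7) with QC + embedding, reused across files.
default_atlas <- function() {
  if (is.null(.fixtures$atlas)) {
    cfg <- sim_config(seed = 7)
    atlas <- make_spatial(make_atlas(cfg))
    qc <- qc_filter(atlas$counts, min_features = 10)
    expr <- suppressWarnings(transform_expr(qc, n_hvg = 3000, n_pcs = 30))
    .fixtures$atlas <- list(cfg = cfg, atlas = atlas, qc = qc, expr = expr)
  }
  .fixtures$atlas
}

# Small expression matrix with iid noise genes (null structure).
null_expr <- function(n_cells, n_genes, seed = 1, mu = 1, size = 10) {
  set.seed(seed)
  cnt <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = size),
                n_cells, n_genes)
  vals <- log1p(cnt / pmax(rowSums(cnt), 1) * stats::median(rowSums(cnt)))
  dimnames(vals) <- list(sprintf("c%04d", seq_len(n_cells)),
                         sprintf("g%04d", seq_len(n_genes)))
  vals
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b); n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Independent two-sided rank-sum p-value by full enumeration of group
# assignments (oracle for the Wilcoxon implementation).
enumerate_wilcox_p <- function(x, in_group) {
  n1 <- sum(in_group)
  n <- length(x)
  r <- rank(x)
  u_obs <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  if (u_obs > n1 * (n - n1) / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}
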