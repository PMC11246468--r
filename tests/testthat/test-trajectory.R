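# Backbone pseudotime, lineage-gene association, modules, vignette graphs,
# fate probabilities.

test_that("collinear clusters give arc-length pseudotime matching the coordinate", {
  set.seed(20)
  x <- c(runif(60, 0, 2), runif(60, 4, 6), runif(60, 8, 10))
  emb <- cbind(x, 0)
  labs <- rep(c("A", "B", "C"), each = 60)
  m <- infer_backbone(emb, labs, "A")
  expect_equal(length(m$lineages), 1)
  expect_equal(unname(m$lineages[[1]]), c("A", "B", "C"))
  # between the end centroids the arc position is exactly the shifted
  # coordinate; beyond them projections clamp to the backbone ends
  cA <- m$centroids["A", 1]; cC <- m$centroids["C", 1]
  inside <- x >= cA & x <= cC
  expect_equal(unname(m$pseudotime[inside]), x[inside] - cA, tolerance = 1e-10)
  expect_equal(stats::cor(m$pseudotime[inside], x[inside], method = "spearman"), 1)
  # cells exactly at the root centroid have pseudotime zero
  root_cent <- m$centroids["A", ]
  emb2 <- rbind(emb, root_cent)
  m2 <- infer_backbone(emb2, c(labs, "A"), "A")
  expect_equal(unname(m2$pseudotime[length(m2$pseudotime)]), 0, tolerance = 1e-12)
})

test_that("the Y-trajectory backbone equals the brute-force MST over centroids", {
  set.seed(21)
  cent <- rbind(A = c(0, 0), B = c(3, 0), C = c(5, 2), D = c(5, -2))
  emb <- cent[rep(1:4, each = 50), ] + matrix(rnorm(400, 0, 0.1), 200, 2)
  labs <- rep(rownames(cent), each = 50)
  m <- infer_backbone(emb, labs, "A")
  got <- m$mst_edges
  got_set <- sort(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
  # oracle: enumerate all spanning trees of the 4 observed centroids
  cc <- m$centroids
  D <- as.matrix(dist(cc))
  all_edges <- t(utils::combn(rownames(cc), 2))
  best <- NULL; best_w <- Inf
  for (pick in utils::combn(nrow(all_edges), 3, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(all_edges[pick, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) == 4 && igraph::is_connected(g)) {
      w <- sum(D[all_edges[pick, , drop = FALSE]])
      if (w < best_w) { best_w <- w; best <- all_edges[pick, , drop = FALSE] }
    }
  }
  want_set <- sort(paste(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])))
  expect_identical(got_set, want_set)
  expect_setequal(got_set, c("A B", "B C", "B D"))
  expect_setequal(names(m$lineages), c("C", "D"))
})

test_that("pseudotime is invariant to rigid rotation of the embedding", {
  fx <- default_atlas()
  emb <- fx$expr$embedding[1:400, 1:10]
  labs <- fx$qc$cell_meta$true_type[1:400]
  m1 <- infer_backbone(emb, labs, "A")
  set.seed(22)
  Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  m2 <- infer_backbone(emb %*% Q, labs, "A")
  expect_equal(m1$pseudotime, m2$pseudotime, tolerance = 1e-8)
})

test_that("spline association keeps planted pseudotime genes and drops null genes", {
  set.seed(23)
  n <- 500
  x <- sort(runif(n, 0, 10))
  emb <- cbind(x, rnorm(n, 0, 0.2))
  labs <- as.character(cut(x, 3, labels = c("A", "B", "C")))
  m <- infer_backbone(emb, labs, "A")
  tau <- m$pseudotime
  nullY <- null_expr(n, 300, seed = 23)
  planted <- sapply(1:20, function(g) {
    act <- 1 / (1 + exp(-12 * (tau / max(tau) - runif(1, 0.3, 0.7))))
    log1p(rnbinom(n, mu = exp(0.3 + 1.5 * act), size = 10))
  })
  colnames(planted) <- sprintf("planted%02d", 1:20)
  res <- suppressWarnings(
    association_test(cbind(nullY, planted), m, fdr = 0.01, df = 10))
  tab <- res[[1]]
  null_kept <- mean(colnames(nullY) %in% tab$selected)
  expect_lte(null_kept, 0.02)
  power <- mean(colnames(planted) %in% tab$selected)
  expect_gte(power, 0.8)
})

test_that("lineage association is assessed on each lineage separately", {
  fx <- default_atlas()
  keep <- fx$qc$cell_meta$true_type %in% c("A", "B", "C", "D")
  m <- infer_backbone(fx$expr$embedding[keep, ], fx$qc$cell_meta$true_type[keep], "A")
  set.seed(24)
  n <- sum(keep)
  # a gene active only past the bifurcation on lineage C
  onC <- fx$qc$cell_meta$true_type[keep] == "C"
  g <- log1p(rnbinom(n, mu = ifelse(onC, 8, 0.5), size = 10))
  Y <- cbind(null_expr(n, 5, seed = 24), lineage_c_gene = g)
  res <- suppressWarnings(association_test(Y, m, fdr = 0.01, df = 10))
  expect_true("lineage_c_gene" %in% res[["C"]]$selected)
  expect_named(res, c("C", "D"), ignore.order = TRUE)
})

test_that("gene modules separate anticorrelated profiles and match a hand-built oracle", {
  set.seed(25)
  tau <- sort(runif(80))
  base <- sin(2 * pi * tau)
  Y <- cbind(g1 = base + rnorm(80, 0, 0.05),
             g2 = base + rnorm(80, 0, 0.05),
             g3 = -base + rnorm(80, 0, 0.05),
             flat = rep(1, 80))
  expect_warning(mod <- gene_modules(Y, tau, colnames(Y), n_modules = 2),
                 "constant genes removed")
  expect_equal(mod$modules[["g1"]], mod$modules[["g2"]])
  expect_false(mod$modules[["g1"]] == mod$modules[["g3"]])
  # identical profiles: distance zero, same module
  Y2 <- cbind(a = base, b = base, c = -base)
  mod2 <- gene_modules(Y2, tau, colnames(Y2), n_modules = 2)
  expect_equal(mod2$modules[["a"]], mod2$modules[["b"]])
  # six block-structured profiles against Ward on a hand-computed matrix
  set.seed(26)
  blockA <- tau; blockB <- cos(3 * tau); blockC <- -tau
  Y3 <- cbind(a1 = blockA + rnorm(80, 0, 0.02), a2 = blockA + rnorm(80, 0, 0.02),
              b1 = blockB + rnorm(80, 0, 0.02), b2 = blockB + rnorm(80, 0, 0.02),
              c1 = blockC + rnorm(80, 0, 0.02), c2 = blockC + rnorm(80, 0, 0.02))
  mod3 <- gene_modules(Y3, tau, colnames(Y3), n_modules = 3)
  ord <- order(tau)
  Dhand <- matrix(0, 6, 6, dimnames = list(colnames(Y3), colnames(Y3)))
  for (i in 1:6) for (j in 1:6)
    Dhand[i, j] <- 1 - stats::cor(Y3[ord, i], Y3[ord, j])
  want <- stats::cutree(stats::hclust(stats::as.dist(Dhand), "ward.D2"), 3)
  expect_equal(ari(mod3$modules, want), 1)
  # smoothed heatmap has one row per gene over the grid
  expect_equal(dim(mod3$smoothed), c(6L, 100L))
})

test_that("vignette bins follow the gestational-week convention", {
  expect_equal(lungdyn:::gw_vignette(c(12, 15, 18)), c("early", "mid", "late"))
  expect_equal(lungdyn:::gw_vignette(17), "late")            # trajectory bins
  expect_true(is.na(lungdyn:::gw_vignette(17, late_start = 18)))  # signaling bins
})

test_that("vignette connectivity matches brute-force edge counting", {
  set.seed(27)
  n <- 90
  emb <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
               matrix(rnorm(60, 1.2, 0.5), 30, 2),
               matrix(rnorm(60, 30, 0.5), 30, 2))
  labs <- rep(c("p", "q", "r"), each = 30)
  gw <- rep(12, n)
  tau <- c(rep(0, 30), rep(1, 30), rep(2, 30))
  vg <- vignette_connectivity(emb, labs, gw, tau, k_neighbors = 10)
  conn <- vg$early$connectivity
  # far-away cluster r: no kNN edges to p or q
  expect_equal(conn["p", "r"], 0)
  expect_equal(conn["q", "r"], 0)
  expect_gt(conn["p", "q"], 0)
  # brute force: recount unique kNN edges between p and q
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  pairs <- matrix(FALSE, n, n)
  for (i in 1:n) {
    nn <- order(d[i, ])[1:10]
    pairs[cbind(pmin(i, nn), pmax(i, nn))] <- TRUE
  }
  idx <- which(pairs, arr.ind = TRUE)
  m_edges <- nrow(idx)
  obs_pq <- sum((labs[idx[, 1]] == "p" & labs[idx[, 2]] == "q") |
                  (labs[idx[, 1]] == "q" & labs[idx[, 2]] == "p"))
  expect_pq <- m_edges * (30 * 30) / (n * (n - 1) / 2)
  expect_equal(unname(conn["p", "q"]), min(1, obs_pq / expect_pq),
               tolerance = 1e-12)
  # orientation runs from lower to higher mean pseudotime
  e <- vg$early$edges
  expect_true(all(e$from == "p" | e$to != "p" | e$from <= e$to))
  expect_equal(e$from[e$to == "q"], "p")
})

test_that("fate probabilities are absorbing, normalized, and match a dense solve", {
  set.seed(28)
  n <- 150
  x <- sort(runif(n, 0, 10))
  emb <- cbind(x, rnorm(n, 0, 0.3))
  labs <- as.character(cut(x, 3, labels = c("root", "mid", "tip")))
  tau <- x
  fate <- fate_probabilities(emb, tau, "tip", labs, k_neighbors = 8)
  expect_true(all(abs(rowSums(fate) - 1) < 1e-8))
  expect_true(all(fate[labs == "tip", "tip"] == 1))
  # dense oracle: rebuild the chain naively and solve with base::solve
  k <- 8
  d <- as.matrix(dist(emb)); diag(d) <- Inf
  scale_ <- {
    dt <- c()
    for (i in 1:n) dt <- c(dt, tau[order(d[i, ])[1:k]] - tau[i])
    stats::sd(dt)
  }
  P <- matrix(0, n, n)
  for (i in 1:n) {
    if (labs[i] == "tip") next
    nn <- order(d[i, ])[1:k]
    w <- 1 / (1 + exp(-(tau[nn] - tau[i]) / scale_))
    P[i, nn] <- w / sum(w)
  }
  absorbing <- which(labs == "tip")
  trans <- setdiff(1:n, absorbing)
  B <- solve(diag(length(trans)) - P[trans, trans],
             rowSums(P[trans, absorbing, drop = FALSE]))
  expect_equal(unname(fate[trans, "tip"]), unname(B), tolerance = 1e-6)
})

test_that("fate probabilities resolve the planted branch past the bifurcation", {
  fx <- default_atlas()
  keep <- fx$qc$cell_meta$true_type %in% c("A", "B", "C", "D")
  ty <- fx$qc$cell_meta$true_type[keep]
  m <- infer_backbone(fx$expr$embedding[keep, ], ty, "A")
  fate <- fate_probabilities(fx$expr$embedding[keep, ], m$pseudotime,
                             c("C", "D"), ty)
  expect_gte(mean(fate[ty == "C", "C"] > 0.9), 0.9)
  expect_gte(mean(fate[ty == "D", "D"] > 0.9), 0.9)
  # pre-branch cells are less committed than post-branch cells
  pre <- ty %in% c("A", "B")
  gap_pre <- mean(abs(fate[pre, "C"] - fate[pre, "D"]))
  gap_post <- mean(abs(fate[!pre, "C"] - fate[!pre, "D"]))
  expect_lt(gap_pre, gap_post)
})

test_that("degenerate trajectory inputs error clearly", {
  emb <- matrix(rnorm(40), 20, 2)
  expect_error(infer_backbone(emb, rep("A", 20), "A"), ">= 2 clusters")
  expect_error(infer_backbone(emb, rep(c("A", "B"), 10), "Z"), "root")
  expect_error(fate_probabilities(emb, rep(0, 20), "Z", rep(c("A", "B"), 10)),
               "terminal")
})
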