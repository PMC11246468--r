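# QC filtering, normalization/HVG/PCA, graph clustering, resolution stability.

toy_counts <- function() {
  # 5 cells x 250 genes (one mitochondrial); detection patterns chosen so the
  # QC boundary cases are exact
  g <- c(sprintf("G%03d", 1:249), "MT-1")
  m <- matrix(0L, 5, 250, dimnames = list(sprintf("c%d", 1:5), g))
  m[1, 1:150] <- 1L                                  # 150 features: removed
  m[2, 1:249] <- 1L; m[2, 250] <- 63L                # mito 63/312 > 0.15: removed
  m[3, 1:240] <- 2L                                  # kept
  m[4, 1:220] <- 1L                                  # kept
  m[5, 21:240] <- 1L                                 # kept
  count_matrix(m, data.frame(cell_id = rownames(m), sample_id = "s1",
                             gestational_week = 12L), g)
}

test_that("QC removes low-feature and high-mito cells and rare genes at the stated boundaries", {
  qc <- qc_filter(toy_counts(), min_features = 200, max_mito_frac = 0.15,
                  min_cells_per_gene = 3)
  expect_setequal(qc$cell_meta$cell_id, c("c3", "c4", "c5"))
  # genes 21..220 are detected in exactly 3 surviving cells: retained
  expect_true("G021" %in% qc$gene_ids)
  # genes 241..249 detected in 0 surviving cells: removed
  expect_false("G241" %in% qc$gene_ids)
  # genes 1..20 detected in 2 surviving cells (< 3): removed
  expect_false("G001" %in% qc$gene_ids)
  expect_error(qc_filter(toy_counts(), min_features = 251), "empty after QC")
})

test_that("QC is idempotent", {
  q1 <- qc_filter(toy_counts(), min_features = 200)
  q2 <- qc_filter(q1, min_features = 200)
  expect_identical(as.matrix(q1$counts), as.matrix(q2$counts))
  expect_identical(q1$cell_meta, q2$cell_meta)
})

test_that("library normalization makes proportional cells identical and keeps values finite", {
  set.seed(1)
  base <- rpois(60, 5) + 1L
  m <- rbind(base, 2L * base, 3L * base,
             matrix(rpois(60 * 7, 5), 7, 60))
  cm <- count_matrix(m, data.frame(cell_id = sprintf("c%d", 1:10),
                                   sample_id = "s1"), sprintf("g%d", 1:60))
  ex <- suppressWarnings(transform_expr(cm, n_hvg = 60, n_pcs = 5))
  expect_equal(as.numeric(ex$values[1, ]), as.numeric(ex$values[2, ]),
               tolerance = 1e-12)
  expect_equal(as.numeric(ex$values[1, ]), as.numeric(ex$values[3, ]),
               tolerance = 1e-12)
  expect_true(all(is.finite(ex$values@x)) && all(ex$values@x >= 0))
})

test_that("a single strongly variable gene is the top HVG", {
  set.seed(2)
  m <- matrix(5L, 40, 5, dimnames = list(sprintf("c%d", 1:40), sprintf("g%d", 1:5)))
  m <- m + matrix(rpois(200, 1), 40, 5)
  m[, 3] <- c(rep(0L, 20), rep(50L, 20))  # huge dispersion
  cm <- count_matrix(m, data.frame(cell_id = rownames(m), sample_id = "s1"),
                     colnames(m))
  ex <- suppressWarnings(transform_expr(cm, n_hvg = 1, n_pcs = 2))
  expect_identical(ex$hvg, "g3")
})

test_that("PCA of rank-2 structured data puts at least 99% of variance in two components", {
  set.seed(3)
  # three archetype expression profiles with equal library size -> the
  # centered log profile matrix has rank 2
  p1 <- rep(c(10L, 2L), each = 15)
  p2 <- rep(c(2L, 10L), each = 15)
  p3 <- rep(c(6L, 6L), each = 15)
  m <- rbind(p1, p2, p3)[rep(1:3, each = 12), ]
  cm <- count_matrix(m, data.frame(cell_id = sprintf("c%d", 1:36),
                                   sample_id = "s1"), sprintf("g%d", 1:30))
  ex <- suppressWarnings(transform_expr(cm, n_hvg = 30, n_pcs = 5))
  v <- apply(ex$embedding, 2, var)
  expect_gte(sum(v[1:2]) / sum(v), 0.99)
  # agreement with an exact SVD of the same scaled matrix
  X <- as.matrix(ex$values[, ex$hvg])
  Xs <- scale(X); Xs[is.na(Xs)] <- 0
  Xs[Xs > 10] <- 10; Xs[Xs < -10] <- -10
  sv <- svd(Xs)$d^2
  expect_gte(sum(sv[1:2]) / sum(sv), 0.99)
})

test_that("clustering separates two well-separated blobs exactly and is seed-deterministic", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(200, 0, 0.3), 100, 2),
               matrix(rnorm(200, 10, 0.3), 100, 2))
  truth <- rep(c(1, 2), each = 100)
  cl1 <- cluster_graph(emb, k_neighbors = 15, resolution = 0.1, seed = 5)
  expect_equal(length(unique(cl1$labels)), 2)
  expect_equal(ari(cl1$labels, truth), 1)
  cl2 <- cluster_graph(emb, k_neighbors = 15, resolution = 0.1, seed = 5)
  expect_identical(cl1$labels, cl2$labels)
  # vanishing resolution collapses a connected graph to one community
  one <- matrix(rnorm(240, 0, 1), 120, 2)
  cl0 <- cluster_graph(one, k_neighbors = 15, resolution = 1e-4, seed = 5)
  expect_equal(length(unique(cl0$labels)), 1)
  expect_error(cluster_graph(emb, k_neighbors = 200), "k_neighbors")
})

test_that("identical labelings across resolutions produce single full-weight parents", {
  labs <- rep(0:2, each = 10)
  l1 <- structure(list(labels = labs, resolution = 0.5, seed = 0),
                  class = "cluster_labels")
  l2 <- structure(list(labels = labs, resolution = 1, seed = 0),
                  class = "cluster_labels")
  rep_ <- resolution_stability(list(l1, l2))
  expect_true(all(rep_$edges$in_proportion == 1))
  expect_length(rep_$flagged_resolutions, 0)
  expect_equal(rep_$recommended_resolution, 1)
})

test_that("a child drawing 60/40 from two parents flags the resolution as over-clustered", {
  par <- c(rep(0, 60), rep(1, 40))
  chi <- rep(0, 100)
  l1 <- structure(list(labels = par, resolution = 0.5, seed = 0),
                  class = "cluster_labels")
  l2 <- structure(list(labels = chi, resolution = 1, seed = 0),
                  class = "cluster_labels")
  rep_ <- resolution_stability(list(l1, l2), in_prop_threshold = 0.1)
  expect_equal(rep_$flagged_resolutions, 1)
  expect_equal(rep_$recommended_resolution, 0.5)
  e <- rep_$edges
  expect_equal(sort(e$in_proportion), c(0.4, 0.6))
})

test_that("in-proportions match hand-counted overlaps and sum to one per child", {
  par <- c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2)
  chi <- c(0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  l1 <- structure(list(labels = par, resolution = 1, seed = 0),
                  class = "cluster_labels")
  l2 <- structure(list(labels = chi, resolution = 2, seed = 0),
                  class = "cluster_labels")
  e <- resolution_stability(list(l1, l2))$edges
  get <- function(p, c) e$in_proportion[e$parent == p & e$child == c]
  expect_equal(get("0", "0"), 1)          # child 0: both cells from parent 0
  expect_equal(get("0", "1"), 0.5)        # child 1: 2/4 from parent 0
  expect_equal(get("1", "1"), 0.5)
  expect_equal(get("1", "2"), 0.25)
  expect_equal(get("2", "2"), 0.75)
  # property: per-child in-proportions always sum to 1
  for (s in 1:5) {
    set.seed(s)
    p <- sample(0:3, 60, replace = TRUE)
    c2 <- sample(0:5, 60, replace = TRUE)
    lp <- structure(list(labels = p, resolution = 1, seed = 0), class = "cluster_labels")
    lc <- structure(list(labels = c2, resolution = 2, seed = 0), class = "cluster_labels")
    ee <- resolution_stability(list(lp, lc))$edges
    sums <- tapply(ee$in_proportion, ee$child, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  expect_error(resolution_stability(list(l1, structure(
    list(labels = chi[1:5], resolution = 2, seed = 0), class = "cluster_labels"))),
    "same cells")
})

test_that("clustering the synthetic atlas recovers planted types (ARI >= 0.9)", {
  # type-level structure sits at coarse resolution; finer resolutions split
  # types by maturation age, which is genuine substructure in the generator
  fx <- default_atlas()
  cl <- cluster_graph(fx$expr$embedding, k_neighbors = 30, resolution = 0.1,
                      seed = 1)
  expect_gte(ari(cl$labels, fx$qc$cell_meta$true_type), 0.9)
})
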