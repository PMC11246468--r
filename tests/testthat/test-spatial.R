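# Co-occurrence profiles, neighborhood enrichment, weight colocalization,
# spatially-close type selection.

test_that("co-occurrence pools neighbors within the radius of any focal cell", {
  map <- data.frame(cell_id = c("f", "x", "y"),
                    x = c(0, 10, 200), y = c(0, 0, 0),
                    type = c("TP", "X", "Y"))
  cp <- cooccurrence_profile(map, "TP", radii = 75)
  expect_equal(unname(cp["75", "X"]), 1)
  expect_equal(unname(cp["75", "Y"]), 0)
  # an infinite radius recovers the global non-focal composition
  set.seed(30)
  big <- data.frame(cell_id = 1:300, x = runif(300, 0, 1000),
                    y = runif(300, 0, 1000),
                    type = sample(c("TP", "a", "b"), 300, TRUE, c(0.2, 0.5, 0.3)))
  cpi <- cooccurrence_profile(big, "TP", radii = 1e6)
  glob <- prop.table(table(big$type[big$type != "TP"]))
  expect_equal(unname(cpi[1, c("a", "b")]), unname(as.numeric(glob[c("a", "b")])),
               tolerance = 1e-12)
  expect_error(cooccurrence_profile(big, "absent"), "focal")
  expect_error(cooccurrence_profile(big, "TP", radii = -1), "radii")
})

test_that("co-occurrence equals an O(n^2) brute-force computation", {
  set.seed(31)
  n <- 800
  map <- data.frame(cell_id = 1:n, x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                    type = sample(c("TP", "a", "b", "c"), n, TRUE))
  radii <- c(50, 75, 150)
  cp <- cooccurrence_profile(map, "TP", radii)
  foc <- which(map$type == "TP")
  oth <- which(map$type != "TP")
  D <- as.matrix(dist(map[, c("x", "y")]))
  for (r in radii) {
    pool <- oth[apply(D[oth, foc, drop = FALSE], 1, min) <= r]
    want <- prop.table(table(factor(map$type[pool], levels = c("a", "b", "c"))))
    expect_equal(unname(cp[as.character(r), ]), unname(as.numeric(want)),
                 tolerance = 1e-12)
  }
  # proportions sum to one at each radius with a non-empty pool
  expect_true(all(abs(rowSums(cp) - 1) < 1e-12))
  # an empty pool reports missing, not zero
  far <- data.frame(cell_id = 1:3, x = c(0, 900, 950), y = c(0, 900, 950),
                    type = c("TP", "a", "b"))
  cpe <- cooccurrence_profile(far, "TP", radii = 10)
  expect_true(all(is.na(cpe)))
})

test_that("neighborhood enrichment is symmetric, seeded, and sign-correct for segregated types", {
  set.seed(32)
  map <- data.frame(cell_id = 1:400,
                    x = c(runif(200, 0, 200), runif(200, 800, 1000)),
                    y = c(runif(200, 0, 200), runif(200, 800, 1000)),
                    type = rep(c("X", "Y"), each = 200))
  z1 <- neighborhood_enrichment(map, radius = 75, n_perms = 200, seed = 9)
  z2 <- neighborhood_enrichment(map, radius = 75, n_perms = 200, seed = 9)
  expect_identical(z1, z2)
  expect_equal(z1, t(z1))
  expect_gt(z1["X", "X"], 5)
  expect_gt(z1["Y", "Y"], 5)
  expect_lt(z1["X", "Y"], -5)
  # observed counts attached and symmetric
  expect_equal(attr(z1, "observed"), t(attr(z1, "observed")))
  expect_error(neighborhood_enrichment(map[map$type == "X", ]), ">= 2")
})

test_that("a pair with zero null variance reports z = 0 with a warning", {
  # a singleton type can never form a same-type edge, so the X-X count is
  # constant under every permutation
  map <- data.frame(cell_id = 1:5,
                    x = c(0, 10, 20, 30, 40), y = rep(0, 5),
                    type = c("X", "Y", "Y", "Y", "Y"))
  expect_warning(z <- neighborhood_enrichment(map, radius = 75, n_perms = 50,
                                              seed = 1), "zero null SD")
  expect_true(any(z == 0))
})

test_that("weight colocalization matches hand-computed Pearson values", {
  w <- matrix(c(0.7, 0.3,
                0.6, 0.4,
                0.2, 0.8,
                0.5, 0.5,
                0.1, 0.9), 5, 2, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:5), c("X", "Y")))
  res <- weight_colocalization(w)
  expect_equal(res$correlation["X", "Y"], -1)     # two-part closure
  expect_equal(diag(res$correlation), c(X = 1, Y = 1))
  # hand computation on a 3-type table
  w3 <- cbind(X = c(0.5, 0.4, 0.1, 0.3, 0.2),
              Y = c(0.3, 0.3, 0.2, 0.4, 0.1),
              Z = c(0.2, 0.3, 0.7, 0.3, 0.7))
  rownames(w3) <- sprintf("s%d", 1:5)
  res3 <- weight_colocalization(w3)
  hand <- function(a, b) {
    am <- mean(a); bm <- mean(b)
    sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  expect_equal(res3$correlation["X", "Y"], hand(w3[, "X"], w3[, "Y"]),
               tolerance = 1e-12)
  expect_equal(res3$correlation["X", "Z"], hand(w3[, "X"], w3[, "Z"]),
               tolerance = 1e-12)
  expect_equal(res3$correlation, t(res3$correlation))
  # duplicate columns are perfectly correlated and adjacent in the order
  w4 <- cbind(w3[, c("X", "Z")] / rowSums(w3[, c("X", "Z")]), 0)
  w4 <- cbind(A = w4[, 1] / 2, B = w4[, 1] / 2, C = w4[, 2])
  res4 <- weight_colocalization(w4)
  expect_equal(res4$correlation["A", "B"], 1)
  ordA <- match("A", res4$order); ordB <- match("B", res4$order)
  expect_equal(abs(ordA - ordB), 1)
  expect_error(weight_colocalization(w3 * 2), "sum to 1")
})

test_that("spatially close types are thresholded correctly", {
  z <- matrix(c(10, 2, -1,
                2, 8, 0.5,
                -1, 0.5, 9), 3, 3,
              dimnames = list(c("TP", "S", "T"), c("TP", "S", "T")))
  expect_equal(proximal_types(z, "TP", threshold = 0), "S")
  expect_equal(proximal_types(z, "TP", threshold = 100), character())
  expect_setequal(proximal_types(z, "TP", threshold = -Inf), c("S", "T"))
  expect_error(proximal_types(z, "missing"), "absent")
  # constructed geometry: only S interleaved with the focal type
  set.seed(33)
  n <- 150
  map <- data.frame(
    cell_id = 1:(3 * n),
    x = c(runif(n, 0, 300), runif(n, 0, 300), runif(n, 700, 1000)),
    y = c(runif(n, 0, 300), runif(n, 0, 300), runif(n, 700, 1000)),
    type = rep(c("TP", "S", "T"), each = n))
  zz <- neighborhood_enrichment(map, radius = 75, n_perms = 200, seed = 2)
  expect_equal(proximal_types(zz, "TP", threshold = 0), "S")
})
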