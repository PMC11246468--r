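# Ligand-receptor probabilities, permutation significance, temporal
# contrasts, pathway information flow.

# tiny expression matrix with constant within-group values so trimmed means
# are exact
lr_toy <- function(lig_a = 1, lig_b = 0, rec_a = 0.5, rec_b = 1) {
  n <- 20
  v <- cbind(LIG = c(rep(lig_a, n), rep(lig_b, n)),
             REC = c(rep(rec_a, n), rep(rec_b, n)),
             BG1 = 0.3, BG2 = 0.2)
  rownames(v) <- sprintf("c%d", 1:(2 * n))
  list(vals = v, labs = rep(c("S", "T"), each = n))
}

db1 <- data.frame(ligand = "LIG", receptor = "REC", pathway = "P",
                  stringsAsFactors = FALSE)

test_that("interaction probability follows the mass-action Hill form exactly", {
  toy <- lr_toy(lig_a = 1, rec_b = 0.5)
  tab <- interaction_probability(toy$vals, toy$labs, db1, hill_k = 0.5)
  st <- tab[tab$sender == "S" & tab$receiver == "T", ]
  expect_equal(st$probability, (1 * 0.5) / (0.5 + 1 * 0.5))   # L*R = k -> 1/2
  expect_equal(st$probability, 0.5)
  # zero ligand in the sender means zero probability
  toy0 <- lr_toy(lig_a = 0, lig_b = 0)
  tab0 <- interaction_probability(toy0$vals, toy0$labs, db1)
  expect_true(all(tab0$probability == 0))
  # saturation toward one for a huge signal
  toyb <- lr_toy(lig_a = 1e6, rec_b = 1e6)
  tabb <- interaction_probability(toyb$vals, toyb$labs, db1)
  expect_gt(tabb$probability[tabb$sender == "S" & tabb$receiver == "T"], 0.999)
  # multi-subunit receptors combine by geometric mean
  v <- matrix(rep(c(1, 4, 1), each = 10), 10, 3,
              dimnames = list(sprintf("c%d", 1:10), c("L", "R1", "R2")))
  db2 <- data.frame(ligand = "L", receptor = "R1;R2", pathway = "P")
  t2 <- interaction_probability(v, rep(c("S", "T"), each = 5), db2, hill_k = 0.5)
  lr <- 1 * sqrt(4 * 1)
  expect_equal(t2$probability[1], lr / (0.5 + lr))
  expect_warning(interaction_probability(v, rep(c("S", "T"), each = 5),
                                         rbind(db2, data.frame(ligand = "NOPE",
                                                               receptor = "R1",
                                                               pathway = "P"))),
                 "missing genes")
})

test_that("interaction probability is monotone in ligand and receptor signal", {
  probs <- sapply(c(0.1, 0.5, 1, 2, 5), function(a)
    with(lr_toy(lig_a = a, rec_b = 1), {
      tab <- interaction_probability(vals, labs, db1)
      tab$probability[tab$sender == "S" & tab$receiver == "T"]
    }))
  expect_true(all(diff(probs) > 0))
})

test_that("permutation significance detects planted pairs and bounds p-values", {
  fx <- default_atlas()
  ty <- fx$qc$cell_meta$true_type
  gw <- fx$qc$cell_meta$gestational_week
  early <- !is.na(lungdyn:::gw_vignette(gw, 18)) &
    lungdyn:::gw_vignette(gw, 18) == "early"
  tab <- permutation_significance(fx$expr$values[early, ], ty[early],
                                  fx$cfg$lr_spec, n_perms = 100, seed = 4)
  planted <- tab[tab$sender == "A" & tab$receiver == "B" & tab$ligand == "LIG1", ]
  expect_true(planted$significant)
  expect_true(all(tab$p_value >= 1 / 101 - 1e-12))
  expect_true(all(tab$p_value <= 1))
  expect_error(permutation_significance(fx$expr$values[early, ], ty[early],
                                        fx$cfg$lr_spec, n_perms = 10),
               "n_perms")
})

test_that("permutation p-values are conservative under an exchangeable null", {
  set.seed(40)
  vals <- null_expr(240, 30, seed = 40)
  labs <- sample(c("S", "T", "U"), 240, replace = TRUE)
  db <- data.frame(ligand = sprintf("g%04d", 1:6),
                   receptor = sprintf("g%04d", 7:12),
                   pathway = sprintf("pw%d", 1:6))
  tab <- permutation_significance(vals, labs, db, n_perms = 100, seed = 7,
                                  alpha = 0.05)
  expect_lte(mean(tab$p_value < 0.05), 0.075)
})

test_that("identical expression across vignettes yields no temporal calls", {
  set.seed(41)
  n <- 240
  vals <- null_expr(n, 20, seed = 41)
  labs <- rep(c("S", "T"), n / 2)
  gw <- rep(c(11, 15, 19), each = n / 3)   # early / mid / late
  db <- data.frame(ligand = "g0001", receptor = "g0002", pathway = "P")
  res <- temporal_compare(vals, labs, gw, db, n_perms = 50, seed = 3)
  expect_true(all(res$call == "none"))
})

test_that("a planted early ligand switch is called early-up and senders can be restricted", {
  fx <- default_atlas()
  ty <- fx$qc$cell_meta$true_type
  gw <- fx$qc$cell_meta$gestational_week
  res <- temporal_compare(fx$expr, ty, gw, fx$cfg$lr_spec,
                          sample_id = fx$qc$cell_meta$sample_id,
                          n_perms = 200, seed = 5)
  ab <- res[res$sender == "A" & res$receiver == "B" & res$ligand == "LIG1", ]
  expect_equal(ab$call, "early_up")
  cd <- res[res$sender == "C" & res$receiver == "D" & res$ligand == "LIG2", ]
  expect_equal(cd$call, "late_up")
  # sender restriction removes excluded senders entirely
  res2 <- temporal_compare(fx$expr, ty, gw, fx$cfg$lr_spec,
                           restrict_senders = c("C"), n_perms = 20, seed = 5,
                           alpha = 0.2)
  expect_true(all(res2$sender == "C"))
  res3 <- temporal_compare(fx$expr, ty, gw, fx$cfg$lr_spec,
                           restrict_senders = list(B = "A", D = "C"),
                           n_perms = 20, seed = 5, alpha = 0.2)
  expect_true(all((res3$receiver == "B" & res3$sender == "A") |
                    (res3$receiver == "D" & res3$sender == "C")))
})

test_that("information flow sums significant probabilities and tests exactly", {
  mk_tab <- function(p) {
    data.frame(sender = "S", receiver = "T",
               ligand = sprintf("L%d", seq_along(p)),
               receptor = sprintf("R%d", seq_along(p)),
               pathway = sprintf("pw%d", seq_along(p)),
               probability = p, p_value = 0.001,
               significant = TRUE, stringsAsFactors = FALSE)
  }
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  fl_same <- information_flow(list(early = mk_tab(a), late = mk_tab(a)))
  expect_equal(fl_same$tests$p_value, 1)
  fl_shift <- information_flow(list(early = mk_tab(a), late = mk_tab(a + 1)))
  expect_equal(fl_shift$tests$p_value, 2 / 256, tolerance = 1e-12)
  # flows are nonnegative and zero for pathways with nothing significant
  t1 <- mk_tab(a); t1$significant[3] <- FALSE
  fl <- information_flow(list(early = t1, late = mk_tab(a)))
  expect_equal(unname(fl$flow["pw3", "early"]), 0)
  expect_true(all(fl$flow >= 0))
  expect_warning(information_flow(list(e = mk_tab(a[1:3]), l = mk_tab(a[1:3]))),
                 "underpowered")
})
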