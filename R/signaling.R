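# Trimmed-mean expression of a set of genes per cell-type group.
# Returns types x genes matrix (25% trimmed mean by default).
group_trimmed_means <- function(vals, labs, genes, trim = 0.25) {
  labs <- as.vector(labs)
  types <- sort(unique(labs))
  out <- matrix(0, length(types), length(genes),
                dimnames = list(types, genes))
  for (ty in types) {
    sub <- as.matrix(vals[labs == ty, genes, drop = FALSE])
    out[ty, ] <- apply(sub, 2, mean, trim = trim)
  }
  out
}

# All distinct permutations of a label multiset (rows of the result).
# Counts stay small here: vignette labels over tens of samples.
multiset_perms <- function(labels, max_rows = 20000) {
  u <- unique(labels)
  cnt <- as.integer(table(factor(labels, levels = u)))
  total <- factorial(length(labels)) / prod(factorial(cnt))
  if (total > max_rows) return(NULL)
  res <- matrix(integer(0), nrow = 0, ncol = length(labels))
  rec <- function(prefix, cnt) {
    if (sum(cnt) == 0) return(matrix(prefix, nrow = 1))
    out <- list()
    for (k in seq_along(cnt)) {
      if (cnt[k] == 0) next
      c2 <- cnt; c2[k] <- c2[k] - 1L
      out[[length(out) + 1]] <- rec(c(prefix, k), c2)
    }
    do.call(rbind, out)
  }
  idx <- rec(integer(0), cnt)
  matrix(u[idx], nrow = nrow(idx))
}

lr_needed_genes <- function(lr_db) {
  unique(c(unlist(strsplit(lr_db$ligand, ";", fixed = TRUE)),
           unlist(strsplit(lr_db$receptor, ";", fixed = TRUE))))
}

# Probabilities for every (sender, receiver, pair) given precomputed
# type x gene trimmed means. Multi-subunit genes combine by geometric mean.
lr_prob_from_means <- function(tm, lr_db, hill_k) {
  types <- rownames(tm)
  rows <- list()
  for (r in seq_len(nrow(lr_db))) {
    lig <- strsplit(lr_db$ligand[r], ";", fixed = TRUE)[[1]]
    rec <- strsplit(lr_db$receptor[r], ";", fixed = TRUE)[[1]]
    Lv <- if (length(lig) == 1) tm[, lig] else apply(tm[, lig, drop = FALSE], 1, geom_mean)
    Rv <- if (length(rec) == 1) tm[, rec] else apply(tm[, rec, drop = FALSE], 1, geom_mean)
    lr <- outer(Lv, Rv)  # senders x receivers
    rows[[r]] <- data.frame(
      sender = rep(types, times = length(types)),
      receiver = rep(types, each = length(types)),
      ligand = lr_db$ligand[r], receptor = lr_db$receptor[r],
      pathway = lr_db$pathway[r],
      probability = as.vector(lr / (hill_k + lr)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Ligand-receptor interaction probabilities between cell types
#'
#' A mass-action Hill form: the ligand signal L is the 25%-trimmed mean of
#' ligand expression in the sender type, the receptor signal R the trimmed
#' mean in the receiver (multi-subunit ligands/receptors combine by the
#' geometric mean of subunit trimmed means), and the interaction
#' probability is `L*R / (hill_k + L*R)`.
#'
#' @param expr `lung_expr` or cells x genes log-normalized matrix.
#' @param labels per-cell type labels (or `cluster_labels`).
#' @param lr_db data.frame with columns ligand, receptor (";"-separated
#'   subunits), pathway.
#' @param hill_k half-saturation constant.
#' @param trim trim fraction of the group means.
#' @return data.frame(sender, receiver, ligand, receptor, pathway,
#'   probability) over all ordered type pairs; pairs whose genes are
#'   missing from the matrix are skipped with a warning.
#' @export
interaction_probability <- function(expr, labels, lr_db, hill_k = 0.5,
                                    trim = 0.25) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  ok <- vapply(seq_len(nrow(lr_db)), function(r) {
    all(c(strsplit(lr_db$ligand[r], ";", fixed = TRUE)[[1]],
          strsplit(lr_db$receptor[r], ";", fixed = TRUE)[[1]]) %in%
          colnames(vals))
  }, TRUE)
  if (any(!ok)) {
    warning("pairs with missing genes skipped: ",
            paste(lr_db$ligand[!ok], collapse = ", "))
    lr_db <- lr_db[ok, , drop = FALSE]
  }
  if (!nrow(lr_db)) stop("no ligand-receptor pairs with measured genes")
  tm <- group_trimmed_means(vals, labs, lr_needed_genes(lr_db), trim)
  lr_prob_from_means(tm, lr_db, hill_k)
}

#' Permutation significance of ligand-receptor interactions
#'
#' Null distribution of interaction probabilities from seeded permutations
#' of the cell-type labels; `p = (1 + #\{null >= observed\}) / (1 +
#' n_perms)`; interactions are significant at `p < alpha`.
#'
#' @inheritParams interaction_probability
#' @param n_perms label permutations (>= 19).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed.
#' @return `interaction_table`: the [interaction_probability()] table plus
#'   `p_value` and `significant`.
#' @export
permutation_significance <- function(expr, labels, lr_db, n_perms = 100,
                                     alpha = 0.01, seed = 0, hill_k = 0.5,
                                     trim = 0.25) {
  if (n_perms < 19) stop("n_perms < 19: alpha unattainable")
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  if (length(unique(labs)) < 2) stop("need >= 2 cell types")
  obs <- interaction_probability(vals, labs, lr_db, hill_k, trim)
  lr_use <- unique(obs[, c("ligand", "receptor", "pathway")])
  genes <- lr_needed_genes(lr_use)
  exceed <- numeric(nrow(obs))
  with_seed(seed, {
    for (i in seq_len(n_perms)) {
      tm <- group_trimmed_means(vals, sample(labs), genes, trim)
      nullp <- lr_prob_from_means(tm, lr_use, hill_k)
      exceed <- exceed + (nullp$probability >= obs$probability - 1e-12)
    }
  })
  obs$p_value <- (1 + exceed) / (1 + n_perms)
  obs$significant <- obs$p_value < alpha
  class(obs) <- c("interaction_table", class(obs))
  obs
}

#' Per-vignette interaction tables
#'
#' Splits cells into developmental vignettes by gestational week (the
#' signaling convention: early GW10-13, mid GW14-16, late GW18-19 by
#' default, leaving GW17 unassigned) and runs
#' [permutation_significance()] within each.
#'
#' @inheritParams permutation_significance
#' @param gestational_week per-cell weeks.
#' @param late_start first week of the late vignette (18 by default).
#' @return named list of `interaction_table`s.
#' @export
vignette_interactions <- function(expr, labels, gestational_week, lr_db,
                                  n_perms = 100, alpha = 0.01, seed = 0,
                                  hill_k = 0.5, late_start = 18) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  vig <- gw_vignette(gestational_week, late_start = late_start)
  out <- list()
  for (v in c("early", "mid", "late")) {
    idx <- which(!is.na(vig) & vig == v)
    if (!length(idx)) next
    tab <- permutation_significance(vals[idx, , drop = FALSE], labs[idx],
                                    lr_db, n_perms, alpha, seed + match(v, c("early", "mid", "late")),
                                    hill_k, trim = 0.25)
    tab$vignette <- v
    out[[v]] <- tab
  }
  out
}

#' Temporal (early vs mid/late) ligand-receptor contrasts
#'
#' For each (sender, receiver, pair) triple, contrasts the early-vignette
#' interaction probability with the best of mid and late against a
#' permutation null built by shuffling the vignette assignment of whole
#' samples (gestational week is a sample-level covariate; permuting cells
#' would split samples across vignettes and understate the between-sample
#' variability). When no sample identity is available the null falls back
#' to shuffling cells within each cell type. Triples are called early-up
#' (or late-up) at `p < alpha` when the probability change is at least
#' `min_delta`. Senders can be restricted to the types spatially close to
#' each receiver ([proximal_types()]); excluded senders are absent from
#' the output.
#'
#' @inheritParams vignette_interactions
#' @param sample_id per-cell sample identifiers (recommended; enables the
#'   sample-level permutation null).
#' @param restrict_senders `NULL`, a character vector of allowed sender
#'   types, or a named list (per receiver type) of allowed senders.
#' @param min_delta minimum absolute probability change for a call
#'   (default 0.3): a temporal switch must rewire the interaction
#'   materially on the probability scale. Rank extremity alone fires at
#'   rate alpha even for flat pairs, and sample-level depth variability
#'   moves null contrasts by as much as ~0.2 at this design size.
#' @return data.frame(sender, receiver, ligand, receptor, pathway,
#'   prob_early, prob_mid, prob_late, delta, p_early, p_late, call) where
#'   call is "early_up", "late_up" or "none".
#' @export
temporal_compare <- function(expr, labels, gestational_week, lr_db,
                             sample_id = NULL, restrict_senders = NULL,
                             n_perms = 100, alpha = 0.01, seed = 0,
                             hill_k = 0.5, late_start = 18, min_delta = 0.3) {
  vals <- if (inherits(expr, "lung_expr")) expr$values else expr
  labs <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  labs <- as.character(labs)
  vig <- gw_vignette(gestational_week, late_start = late_start)
  keep <- !is.na(vig)
  vals <- vals[keep, , drop = FALSE]
  labs <- labs[keep]; vig <- vig[keep]
  samp <- if (is.null(sample_id)) NULL else as.character(sample_id)[keep]
  vigs <- intersect(c("early", "mid", "late"), unique(vig))
  if (length(vigs) < 2) stop("need cells in >= 2 vignettes")
  genes <- lr_needed_genes(lr_db)
  miss <- setdiff(genes, colnames(vals))
  if (length(miss)) {
    warning("genes absent from matrix treated as probability 0: ",
            paste(miss, collapse = ", "))
    drop <- vapply(seq_len(nrow(lr_db)), function(r)
      any(c(strsplit(lr_db$ligand[r], ";", fixed = TRUE)[[1]],
            strsplit(lr_db$receptor[r], ";", fixed = TRUE)[[1]]) %in% miss), TRUE)
    lr_db <- lr_db[!drop, , drop = FALSE]
    genes <- lr_needed_genes(lr_db)
  }

  probs_by_vig <- function(vg) {
    out <- list()
    for (v in vigs) {
      idx <- which(vg == v)
      tm <- group_trimmed_means(vals[idx, , drop = FALSE], labs[idx], genes)
      # types absent from a vignette contribute zero signal
      types_all <- sort(unique(labs))
      if (!all(types_all %in% rownames(tm))) {
        full <- matrix(0, length(types_all), length(genes),
                       dimnames = list(types_all, genes))
        full[rownames(tm), ] <- tm
        tm <- full
      }
      out[[v]] <- lr_prob_from_means(tm, lr_db, hill_k)$probability
    }
    out
  }
  base <- lr_prob_from_means(
    matrix(0, length(unique(labs)), length(genes),
           dimnames = list(sort(unique(labs)), genes)), lr_db, hill_k)
  obs <- probs_by_vig(vig)
  p_early_obs <- obs[["early"]] %||% rep(0, nrow(base))
  p_mid_obs <- obs[["mid"]] %||% rep(0, nrow(base))
  p_late_obs <- obs[["late"]] %||% rep(0, nrow(base))
  delta <- p_early_obs - pmax(p_mid_obs, p_late_obs)

  cnt_early <- numeric(nrow(base)); cnt_late <- numeric(nrow(base))
  arr <- NULL
  if (!is.null(samp)) {
    su <- unique(samp)
    svig <- vig[match(su, samp)]
    arr <- multiset_perms(svig)
  }
  if (!is.null(arr)) {
    # exact null: every distinct assignment of vignettes to samples, the
    # observed assignment included. Trimmed means are cached per distinct
    # sample subset (arrangements share vignette slots heavily).
    cache <- new.env(parent = emptyenv())
    types_all <- sort(unique(labs))
    tm_subset <- function(ss) {
      key <- paste(sort(ss), collapse = "|")
      got <- cache[[key]]
      if (!is.null(got)) return(got)
      idx <- which(samp %in% ss)
      tm <- group_trimmed_means(vals[idx, , drop = FALSE], labs[idx], genes)
      if (!all(types_all %in% rownames(tm))) {
        full <- matrix(0, length(types_all), length(genes),
                       dimnames = list(types_all, genes))
        full[rownames(tm), ] <- tm
        tm <- full
      }
      p <- lr_prob_from_means(tm, lr_db, hill_k)$probability
      cache[[key]] <- p
      p
    }
    for (i in seq_len(nrow(arr))) {
      pe <- if (any(arr[i, ] == "early")) tm_subset(su[arr[i, ] == "early"]) else 0
      pm <- if (any(arr[i, ] == "mid")) tm_subset(su[arr[i, ] == "mid"]) else 0
      pl <- if (any(arr[i, ] == "late")) tm_subset(su[arr[i, ] == "late"]) else 0
      d <- pe - pmax(pm, pl)
      cnt_early <- cnt_early + (d >= delta - 1e-12)
      cnt_late <- cnt_late + (-d >= -delta - 1e-12)
    }
    p_early_perm <- cnt_early / nrow(arr)
    p_late_perm <- cnt_late / nrow(arr)
  } else {
    with_seed(seed, {
      for (i in seq_len(n_perms)) {
        if (!is.null(samp)) {
          vg <- svig[sample(length(su))][match(samp, su)]
        } else {
          vg <- vig
          for (ty in unique(labs)) {
            ix <- which(labs == ty)
            vg[ix] <- vg[ix][sample(length(ix))]
          }
        }
        nn <- probs_by_vig(vg)
        d <- (nn[["early"]] %||% 0) - pmax(nn[["mid"]] %||% 0, nn[["late"]] %||% 0)
        cnt_early <- cnt_early + (d >= delta - 1e-12)
        cnt_late <- cnt_late + (-d >= -delta - 1e-12)
      }
    })
    p_early_perm <- (1 + cnt_early) / (1 + n_perms)
    p_late_perm <- (1 + cnt_late) / (1 + n_perms)
  }
  res <- data.frame(base[, c("sender", "receiver", "ligand", "receptor", "pathway")],
                    prob_early = p_early_obs, prob_mid = p_mid_obs,
                    prob_late = p_late_obs, delta = delta,
                    p_early = p_early_perm,
                    p_late = p_late_perm,
                    stringsAsFactors = FALSE)
  res$call <- ifelse(res$p_early < alpha & res$delta >= min_delta, "early_up",
                     ifelse(res$p_late < alpha & res$delta <= -min_delta,
                            "late_up", "none"))
  if (!is.null(restrict_senders)) {
    if (is.list(restrict_senders)) {
      keep <- vapply(seq_len(nrow(res)), function(i) {
        allowed <- restrict_senders[[res$receiver[i]]]
        !is.null(allowed) && res$sender[i] %in% allowed
      }, TRUE)
    } else keep <- res$sender %in% restrict_senders
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Pathway information flow and paired signed-rank contrasts
#'
#' Information flow is the sum of significant interaction probabilities per
#' pathway per vignette. Each pair of vignettes is compared with a paired
#' Wilcoxon signed-rank test across pathways (exact for 25 or fewer
#' pathways; identical flows give p = 1 by convention).
#'
#' @param tables named list of `interaction_table`s (one per vignette),
#'   e.g. from [vignette_interactions()].
#' @return list(`flow` pathways x vignettes matrix, `tests`
#'   data.frame(vignette_a, vignette_b, p_value)).
#' @export
information_flow <- function(tables) {
  if (length(tables) < 2) stop("need >= 2 vignettes")
  paths <- sort(unique(unlist(lapply(tables, function(t) t$pathway))))
  if (length(paths) < 5)
    warning("fewer than 5 pathways; the paired test is underpowered")
  flow <- vapply(tables, function(t) {
    s <- t[t$significant, , drop = FALSE]
    f <- tapply(s$probability, factor(s$pathway, levels = paths), sum)
    ifelse(is.na(f), 0, f)
  }, numeric(length(paths)))
  rownames(flow) <- paths
  vs <- names(tables)
  tests <- list()
  for (a in seq_along(vs)) for (b in seq_along(vs)) {
    if (a >= b) next
    tests[[length(tests) + 1]] <- data.frame(
      vignette_a = vs[a], vignette_b = vs[b],
      p_value = paired_signed_rank(flow[, a], flow[, b]))
  }
  list(flow = flow, tests = do.call(rbind, tests))
}

# Two-sided paired Wilcoxon signed-rank p-value. Zero differences are
# dropped (p = 1 if none remain). For n <= exact_max the exact sign-flip
# distribution is computed by dynamic programming over (doubled) midranks,
# which stays exact under ties; larger n falls back to the normal
# approximation with tie correction.
paired_signed_rank <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    ri <- as.integer(round(2 * r))      # doubled midranks are integers
    tot <- sum(ri)
    cnt <- numeric(tot + 1)             # counts over V2 = 0..tot
    cnt[1] <- 1
    for (w in ri) {
      shifted <- c(numeric(w), cnt[seq_len(tot + 1 - w)])
      cnt <- cnt + shifted
    }
    cnt <- cnt / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(cnt[seq_len(v2 + 1)])
    p_ge <- sum(cnt[(v2 + 1):(tot + 1)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  ties <- table(r)
  mu <- n * (n + 1) / 4
  sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  z <- (v - mu) / sg
  min(1, 2 * pnorm(-abs(z)))
}
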