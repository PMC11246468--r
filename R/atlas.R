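#' Simulation configuration for a synthetic developmental atlas
#'
#' Defines the generative model for a seeded synthetic single-cell atlas with
#' the statistical structure the downstream analyses assume: cell types with
#' planted marker genes, per-sample composition trends that are constant,
#' linear or quadratic in gestational week on the logit scale, a branching
#' latent trajectory with pseudotime-dependent genes, spatially organized
#' niches, and ligand-receptor pairs whose sender activity is confined to a
#' developmental vignette.
#'
#' @param n_samples number of tissue samples; each sample has one
#'   gestational week (default 19, one fetal lung tissue per week with the
#'   range cycled).
#' @param gw_range integer vector of length 2, gestational-week range
#'   (inclusive); must lie within 10-19.
#' @param n_cells_per_sample cells drawn per sample.
#' @param n_genes total genes.
#' @param cell_types character vector of type names.
#' @param markers_per_type number of marker genes planted per type (disjoint
#'   blocks).
#' @param marker_effect log-scale mean shift of a marker in its own type
#'   (>= 0).
#' @param composition_spec named list (one entry per cell type) of
#'   `list(family = "constant"|"linear"|"quadratic", beta = c(...))` with
#'   logit-scale coefficients of the polynomial in centered gestational week.
#' @param trajectory_spec `list(paths = list(...), n_genes = , effect = )`:
#'   ordered root-to-leaf cluster paths sharing a common prefix (a branch),
#'   the number of pseudotime-dependent genes, and their log-scale amplitude.
#' @param spatial_spec `list(niches = list(list(center =, radius =,
#'   mixture = named numeric summing to 1)), cells_per_niche = ,
#'   spot_grid = )`; coordinates live on \[0, 1000\]^2 so that a
#'   neighbourhood radius of 75 units is meaningful at default density.
#' @param maturation_spec `list(n_genes = , effect = )`: genes tracking
#'   gestational age across all cell types, with logistic activation windows
#'   staggered over the week range (the maturation program that makes
#'   developmental stages transcriptionally distinguishable).
#' @param lr_spec data.frame with columns ligand, receptor (";"-separated
#'   subunits), pathway, sender, receiver, vignette ("early", "mid", "late"
#'   or "all"): planted ligand-receptor interactions.
#' @param lr_effect log-scale boost of a planted ligand in its sender during
#'   its active vignette.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param base_signal baseline mean of marker/trajectory/ligand genes.
#' @param seed integer seed for the sampling noise; the atlas is a
#'   deterministic function of the configuration.
#' @param program_seed seed of the gene programs (baseline means, activation
#'   windows, directions). Kept separate from `seed` so that atlases drawn
#'   with different seeds share the same biology and differ only in
#'   sampling noise -- a query generated from the same configuration is a
#'   replicate of the reference, as for real tissue.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 19,
                       gw_range = c(10L, 19L),
                       n_cells_per_sample = 300,
                       n_genes = 600,
                       cell_types = c("A", "B", "C", "D"),
                       markers_per_type = 10,
                       marker_effect = 1,
                       composition_spec = NULL,
                       trajectory_spec = list(paths = list(c("A", "B", "C"), c("A", "B", "D")),
                                              n_genes = 60, effect = 1.5),
                       spatial_spec = list(
                         niches = list(
                           list(center = c(300, 300), radius = 220,
                                mixture = c(A = 0.6, B = 0.3, C = 0.05, D = 0.05)),
                           list(center = c(700, 700), radius = 220,
                                mixture = c(A = 0.05, B = 0.25, C = 0.35, D = 0.35))
                         ),
                         cells_per_niche = 400, spot_grid = 10
                       ),
                       maturation_spec = list(n_genes = 40, effect = 1.2),
                       lr_spec = default_lr_spec(),
                       lr_effect = 2,
                       nb_size = 10,
                       base_signal = 2,
                       seed = 1L,
                       program_seed = 777L) {
  if (is.null(composition_spec)) {
    composition_spec <- list(
      A = list(family = "linear", beta = c(0.3, -0.35)),
      B = list(family = "constant", beta = -0.4),
      C = list(family = "linear", beta = c(-0.6, 0.3)),
      D = list(family = "quadratic", beta = c(-0.4, 0.05, -0.08))
    )
  }
  cfg <- list(n_samples = as.integer(n_samples), gw_range = as.integer(gw_range),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              n_genes = as.integer(n_genes), cell_types = cell_types,
              markers_per_type = as.integer(markers_per_type),
              marker_effect = marker_effect, composition_spec = composition_spec,
              trajectory_spec = trajectory_spec, spatial_spec = spatial_spec,
              maturation_spec = maturation_spec,
              lr_spec = lr_spec, lr_effect = lr_effect, nb_size = nb_size,
              base_signal = base_signal, seed = as.integer(seed),
              program_seed = as.integer(program_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted ligand-receptor interactions
#'
#' Two planted pairs: an early-vignette WNT-like signal from type A to type B
#' (two-subunit receptor) and a late-vignette FGF-like signal from type C to
#' type D.
#' @return data.frame with columns ligand, receptor, pathway, sender,
#'   receiver, vignette.
#' @export
default_lr_spec <- function() {
  data.frame(
    ligand = c("LIG1", "LIG2"),
    receptor = c("REC1A;REC1B", "REC2"),
    pathway = c("PATH1", "PATH2"),
    sender = c("A", "C"),
    receiver = c("B", "D"),
    vignette = c("early", "late"),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cnt <- c(n_samples = cfg$n_samples, n_cells_per_sample = cfg$n_cells_per_sample,
           n_genes = cfg$n_genes, markers_per_type = cfg$markers_per_type)
  bad <- names(cnt)[cnt < 1]
  if (length(bad)) stop("configuration error: field(s) ", paste(bad, collapse = ", "),
                        " must be >= 1")
  if (cfg$gw_range[1] < 10 || cfg$gw_range[2] > 19 || cfg$gw_range[1] > cfg$gw_range[2])
    stop("configuration error: gw_range must be an increasing range within 10-19")
  if (!all(cfg$cell_types %in% names(cfg$composition_spec)))
    stop("configuration error: composition_spec missing entries for some cell_types")
  for (ty in cfg$cell_types) {
    cs <- cfg$composition_spec[[ty]]
    want <- switch(cs$family, constant = 1, linear = 2, quadratic = 3,
                   stop("configuration error: composition_spec family for ", ty))
    if (length(cs$beta) != want)
      stop("configuration error: composition_spec beta length for type ", ty)
  }
  paths <- cfg$trajectory_spec$paths
  if (length(paths)) {
    if (!all(unlist(paths) %in% cfg$cell_types))
      stop("configuration error: trajectory_spec paths reference unknown cell types")
    roots <- vapply(paths, `[`, "", 1)
    if (length(unique(roots)) != 1)
      stop("configuration error: trajectory_spec paths must share a root")
  }
  n_lr_genes <- if (nrow(cfg$lr_spec))
    length(unique(c(cfg$lr_spec$ligand,
                    unlist(strsplit(cfg$lr_spec$receptor, ";", fixed = TRUE))))) else 0
  need <- length(cfg$cell_types) * cfg$markers_per_type +
    (cfg$trajectory_spec$n_genes %||% 0) +
    (cfg$maturation_spec$n_genes %||% 0) + n_lr_genes
  if (need > cfg$n_genes)
    stop("configuration error: n_genes too small for markers_per_type + ",
         "trajectory_spec$n_genes + ligand/receptor genes (need ", need, ")")
  for (ni in seq_along(cfg$spatial_spec$niches %||% list())) {
    mix <- cfg$spatial_spec$niches[[ni]]$mixture
    if (length(mix) == 0)
      stop("configuration error: spatial_spec niche ", ni, " has empty mixture")
    if (abs(sum(mix) - 1) > 1e-8)
      stop("configuration error: spatial_spec niche ", ni, " mixture must sum to 1")
    if (!all(names(mix) %in% cfg$cell_types))
      stop("configuration error: spatial_spec niche ", ni, " mixture names unknown")
  }
  invisible(cfg)
}

# Expected type proportions at one gestational week: inverse-logit of the
# configured polynomial in centered GW, renormalized across types.
composition_probs <- function(cfg, gw) {
  ctr <- mean(cfg$gw_range)
  t <- gw - ctr
  p <- vapply(cfg$cell_types, function(ty) {
    b <- cfg$composition_spec[[ty]]$beta
    eta <- b[1] + (if (length(b) > 1) b[2] * t else 0) +
      (if (length(b) > 2) b[3] * t^2 else 0)
    invlogit(eta)
  }, 0)
  p / sum(p)
}

# Map gestational weeks to developmental vignettes. late_start = 18 follows
# the ligand-receptor convention (GW17 unassigned); 17 the trajectory one.
gw_vignette <- function(gw, late_start = 17) {
  v <- rep(NA_character_, length(gw))
  v[gw >= 10 & gw <= 13] <- "early"
  v[gw >= 14 & gw <= 16] <- "mid"
  v[gw >= late_start & gw <= 19] <- "late"
  v
}

#' Generate a synthetic atlas with ground truth
#'
#' Draws a seeded synthetic counts matrix plus per-cell metadata from the
#' generative model in [sim_config()]: per-sample type composition follows
#' the configured logit-scale polynomial in gestational week (renormalized
#' across types); marker genes get an `exp(marker_effect)` mean shift in
#' their own type; trajectory genes follow logistic activation profiles
#' along a latent pseudotime on \[0, 1\]; planted ligands are boosted in
#' their sender type during their active vignette. Counts are negative
#' binomial with per-cell depth scaling.
#'
#' @param cfg a [sim_config()] object.
#' @return object of class `synthetic_atlas`: a list with `counts`
#'   (a `count_matrix`), `truth_markers`, `truth_pseudotime`, `truth_branch`,
#'   `truth_composition`, `lr_truth`, `lr_genes`, and (once
#'   [make_spatial()] has been called) `spatial` and `spot_weights`.
#' @export
make_atlas <- function(cfg) {
  validate_sim_config(cfg)
  types <- cfg$cell_types
  n_types <- length(types)
  G <- cfg$n_genes

  # gene architecture: [markers | trajectory | LR | maturation | background]
  mk_idx <- matrix(seq_len(n_types * cfg$markers_per_type),
                   nrow = cfg$markers_per_type)
  colnames(mk_idx) <- types
  n_traj <- cfg$trajectory_spec$n_genes %||% 0
  traj_idx <- seq_len(n_traj) + n_types * cfg$markers_per_type
  lr_genes <- if (nrow(cfg$lr_spec))
    unique(c(cfg$lr_spec$ligand,
             unlist(strsplit(cfg$lr_spec$receptor, ";", fixed = TRUE)))) else character()
  lr_idx <- seq_along(lr_genes) + n_types * cfg$markers_per_type + n_traj
  n_mat <- cfg$maturation_spec$n_genes %||% 0
  mat_idx <- seq_len(n_mat) + n_types * cfg$markers_per_type + n_traj +
    length(lr_genes)

  gene_ids <- sprintf("G%04d", seq_len(G))
  gene_ids[lr_idx] <- lr_genes
  signal <- c(as.vector(mk_idx), traj_idx, lr_idx, mat_idx)

  # gene programs are the biology: drawn under program_seed so that atlases
  # with different sampling seeds are replicates of the same tissue
  prog <- with_seed(cfg$program_seed, {
    base <- exp(rnorm(G, log(0.2), 1))
    base[signal] <- cfg$base_signal * exp(rnorm(length(signal), 0, 0.2))
    # ligands are switch-like: low baseline, strong when active, so the
    # interaction probability is not saturated before the planted boost
    lig_ids <- if (nrow(cfg$lr_spec))
      unique(unlist(strsplit(cfg$lr_spec$ligand, ";", fixed = TRUE))) else character()
    lig_ix <- match(lig_ids, gene_ids)
    base[lig_ix] <- 0.3 * exp(rnorm(length(lig_ix), 0, 0.2))
    list(base = base,
         traj = list(t0_u = runif(n_traj), slope = runif(n_traj, 15, 25),
                     dirn = sample(c(-1, 1), n_traj, replace = TRUE)),
         mat = list(w0 = runif(n_mat, 9.5, 19.5), ws = runif(n_mat, 2, 4),
                    wdir = sample(c(-1, 1), n_mat, replace = TRUE)))
  })
  base <- prog$base

  with_seed(cfg$seed, {
    gw <- rep(seq(cfg$gw_range[1], cfg$gw_range[2]), length.out = cfg$n_samples)
    gw <- sort(gw)
    sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))

    # per-sample type counts from the composition model
    cells <- list()
    for (s in seq_len(cfg$n_samples)) {
      p <- composition_probs(cfg, gw[s])
      cnt <- as.vector(rmultinom(1, cfg$n_cells_per_sample, p))
      cells[[s]] <- data.frame(
        sample_id = sample_ids[s], gestational_week = gw[s],
        true_type = rep(types, cnt), stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, cells)
    N <- nrow(meta)
    meta$cell_id <- sprintf("cell%05d", seq_len(N))

    # latent pseudotime and branch along the configured paths
    paths <- cfg$trajectory_spec$paths
    tau <- rep(NA_real_, N)
    branch <- rep(NA_character_, N)
    if (length(paths)) {
      traj_types <- unique(unlist(paths))
      in_paths <- lapply(types, function(ty) which(vapply(paths, function(p) ty %in% p, TRUE)))
      names(in_paths) <- types
      for (i in which(meta$true_type %in% traj_types)) {
        ty <- meta$true_type[i]
        pick <- in_paths[[ty]]
        pi <- if (length(pick) > 1) sample(pick, 1) else pick
        path <- paths[[pi]]
        pos <- match(ty, path) - 1L
        L <- length(path)
        tau[i] <- runif(1, pos / L, (pos + 1) / L)
        branch[i] <- if (length(in_paths[[ty]]) > 1) "trunk" else path[length(path)]
      }
    }
    meta$true_pseudotime <- tau
    meta$true_branch <- branch

    # log-mean matrix (genes x cells)
    depth <- exp(rnorm(cfg$n_samples, 0, 0.2))[match(meta$sample_id, sample_ids)] *
      exp(rnorm(N, 0, 0.1))
    logmu <- matrix(log(base), G, N) +
      matrix(log(depth), G, N, byrow = TRUE)

    for (ty in types) {
      cols <- which(meta$true_type == ty)
      logmu[mk_idx[, ty], cols] <- logmu[mk_idx[, ty], cols] + cfg$marker_effect
    }

    if (n_traj > 0 && length(paths)) {
      # shared prefix of the paths: the trunk; branches diverge after it
      shared <- paths[[1]]
      for (p in paths[-1]) {
        k <- 0
        while (k < min(length(shared), length(p)) && shared[k + 1] == p[k + 1])
          k <- k + 1
        shared <- shared[seq_len(k)]
      }
      bif <- length(shared) / max(lengths(paths))
      branching <- length(paths) > 1 && bif < 1
      # half the genes follow the shared trunk program (activation before the
      # bifurcation, common to all branches); the rest are branch programs
      # switching on after it, frozen at the bifurcation off their branch
      n_trunk <- if (branching) ceiling(n_traj / 3) else n_traj
      is_trunk <- seq_len(n_traj) <= n_trunk
      lo <- ifelse(is_trunk, 0.08, min(bif + 0.15, 0.8))
      hi <- ifelse(is_trunk, if (branching) max(0.2, bif - 0.2) else 0.9, 0.85)
      t0 <- lo + prog$traj$t0_u * (hi - lo)
      slope <- prog$traj$slope
      dirn <- prog$traj$dirn
      gene_path <- rep(seq_along(paths), length.out = n_traj)
      on_traj <- which(!is.na(tau))
      amp <- cfg$trajectory_spec$effect %||% 1.5
      for (g in seq_len(n_traj)) {
        te <- tau[on_traj]
        if (!is_trunk[g] && branching) {
          gp <- paths[[gene_path[g]]]
          off_branch <- !(meta$true_type[on_traj] %in% gp)
          te[off_branch] <- pmin(te[off_branch], bif)
        }
        act <- 1 / (1 + exp(-slope[g] * (te - t0[g])))
        eff <- amp * if (dirn[g] > 0) act else (1 - act)
        logmu[traj_idx[g], on_traj] <- logmu[traj_idx[g], on_traj] + eff
      }
    }

    if (n_mat > 0) {
      w0 <- prog$mat$w0
      ws <- prog$mat$ws
      wdir <- prog$mat$wdir
      wact <- 1 / (1 + exp(-outer(ws, meta$gestational_week) + ws * w0))
      weff <- (cfg$maturation_spec$effect %||% 1.2) *
        (ifelse(wdir > 0, 1, 0) * wact + ifelse(wdir > 0, 0, 1) * (1 - wact))
      logmu[mat_idx, ] <- logmu[mat_idx, ] + weff
    }

    lr_truth <- cfg$lr_spec
    if (nrow(lr_truth)) {
      vig <- gw_vignette(meta$gestational_week, late_start = 18)
      for (r in seq_len(nrow(lr_truth))) {
        lig <- match(lr_truth$ligand[r], gene_ids)
        subs <- match(strsplit(lr_truth$receptor[r], ";", fixed = TRUE)[[1]], gene_ids)
        snd <- which(meta$true_type == lr_truth$sender[r] &
                       (lr_truth$vignette[r] == "all" |
                          (!is.na(vig) & vig == lr_truth$vignette[r])))
        rcv <- which(meta$true_type == lr_truth$receiver[r])
        if (length(snd)) logmu[lig, snd] <- logmu[lig, snd] + cfg$lr_effect
        if (length(rcv)) logmu[subs, rcv] <- logmu[subs, rcv] + 1.5
      }
    }

    counts <- matrix(rnbinom(G * N, mu = exp(logmu), size = cfg$nb_size), G, N)
    counts <- Matrix::Matrix(t(counts), sparse = TRUE)  # cells x genes
    rownames(counts) <- meta$cell_id
    colnames(counts) <- gene_ids

    cm <- count_matrix(counts, meta[, c("cell_id", "sample_id", "gestational_week",
                                        "true_type", "true_pseudotime", "true_branch")],
                       gene_ids)
    truth_markers <- lapply(types, function(ty) gene_ids[mk_idx[, ty]])
    names(truth_markers) <- types

    atlas <- list(counts = cm,
                  truth_markers = truth_markers,
                  truth_traj_genes = gene_ids[traj_idx],
                  truth_gw_genes = gene_ids[mat_idx],
                  truth_pseudotime = setNames(tau, meta$cell_id),
                  truth_branch = setNames(branch, meta$cell_id),
                  truth_composition = cfg$composition_spec,
                  lr_truth = lr_truth, lr_genes = lr_genes,
                  config = cfg)
    class(atlas) <- "synthetic_atlas"
    atlas
  })
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cm <- x$counts
  cat("Synthetic atlas:", nrow(cm$counts), "cells x", ncol(cm$counts), "genes;",
      length(unique(cm$cell_meta$sample_id)), "samples, GW",
      paste(range(cm$cell_meta$gestational_week), collapse = "-"), "\n")
  cat("  types:", paste(names(x$truth_markers), collapse = ", "), "\n")
  if (!is.null(x$spatial))
    cat("  spatial map:", nrow(x$spatial), "cells;",
        nrow(x$spot_weights$weights), "spots\n")
  invisible(x)
}

#' Generate spatial centroids and spot deconvolution weights
#'
#' Places cells in configured niches (uniform within each niche disc, types
#' drawn from the niche mixture) on a \[0, 1000\]^2 domain, and summarizes
#' local type composition on a regular grid of pseudo-spots whose weight
#' rows sum to 1 (spots covering no cells are dropped).
#'
#' @param atlas a `synthetic_atlas` (used for the seed and type universe).
#' @param cfg the [sim_config()]; `spatial_spec` must be present.
#' @return the atlas with `spatial` (data.frame cell_id, x, y, type) and
#'   `spot_weights` (list weights, coords) filled in.
#' @export
make_spatial <- function(atlas, cfg = atlas$config) {
  spec <- cfg$spatial_spec
  if (is.null(spec) || !length(spec$niches))
    stop("configuration error: spatial_spec with at least one niche is required")
  validate_sim_config(cfg)
  with_seed(cfg$seed + 1L, {
    per <- spec$cells_per_niche %||% 400
    rows <- list()
    for (ni in seq_along(spec$niches)) {
      nc <- spec$niches[[ni]]
      mix <- nc$mixture
      ty <- sample(names(mix), per, replace = TRUE, prob = mix)
      rr <- nc$radius * sqrt(runif(per))
      th <- runif(per, 0, 2 * pi)
      rows[[ni]] <- data.frame(
        x = pmin(pmax(nc$center[1] + rr * cos(th), 0), 1000),
        y = pmin(pmax(nc$center[2] + rr * sin(th), 0), 1000),
        type = ty, stringsAsFactors = FALSE)
    }
    sp <- do.call(rbind, rows)
    sp <- data.frame(cell_id = sprintf("sp%05d", seq_len(nrow(sp))), sp,
                     stringsAsFactors = FALSE)

    grid <- spec$spot_grid %||% 10
    step <- 1000 / grid
    gx <- pmin(floor(sp$x / step), grid - 1)
    gy <- pmin(floor(sp$y / step), grid - 1)
    spot <- gx + grid * gy
    types <- cfg$cell_types
    tab <- table(factor(spot, levels = 0:(grid^2 - 1)),
                 factor(sp$type, levels = types))
    tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
    keep <- rowSums(tab) > 0
    w <- tab[keep, , drop = FALSE] / rowSums(tab[keep, , drop = FALSE])
    ids <- as.integer(rownames(tab)[keep])
    coords <- data.frame(spot_id = sprintf("spot%03d", ids),
                         x = (ids %% grid + 0.5) * step,
                         y = (ids %/% grid + 0.5) * step)
    rownames(w) <- coords$spot_id
    atlas$spatial <- sp
    atlas$spot_weights <- list(weights = w, coords = coords)
    atlas
  })
}
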