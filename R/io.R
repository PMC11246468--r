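#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (cells x genes), `genes.tsv` (one id per line) and
#' `cells.tsv` (tab-separated metadata with a header).
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from MatrixMarket + TSV sidecars
#'
#' Expects the layout written by [write_count_matrix()]; `cells.tsv` must
#' contain at least `cell_id` and `sample_id`.
#'
#' @param dir directory containing matrix.mtx, genes.tsv, cells.tsv.
#' @param require_gw require a gestational_week column.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(dir, require_gw = FALSE) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cells.tsv"),
                            stringsAsFactors = FALSE)
  for (col in c("cell_id", "sample_id"))
    if (!col %in% names(meta))
      stop("schema error: cells.tsv missing column ", col)
  if (require_gw && !"gestational_week" %in% names(meta))
    stop("schema error: cells.tsv missing column gestational_week")
  count_matrix(m, meta, genes)
}

#' Write a full synthetic atlas (counts, spatial, ground truth)
#'
#' Counts go to `counts/` via [write_count_matrix()]; the spatial map to
#' `spatial.csv`, spot weights to `spot_weights.csv`, the planted
#' ligand-receptor table to `lr_truth.csv`, and the remaining ground truth
#' (markers, composition coefficients) to `truth.yaml`.
#'
#' @param atlas a [make_atlas()] result (after [make_spatial()] if spatial
#'   outputs are wanted).
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(atlas$counts, file.path(dir, "counts"))
  if (!is.null(atlas$spatial)) {
    utils::write.csv(atlas$spatial, file.path(dir, "spatial.csv"),
                     row.names = FALSE, quote = FALSE)
    w <- atlas$spot_weights
    utils::write.csv(data.frame(w$coords, w$weights, check.names = FALSE),
                     file.path(dir, "spot_weights.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (nrow(atlas$lr_truth))
    utils::write.csv(atlas$lr_truth, file.path(dir, "lr_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  truth <- list(markers = atlas$truth_markers,
                trajectory_genes = atlas$truth_traj_genes,
                composition = atlas$truth_composition)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a spatial map CSV
#' @param path CSV with columns cell_id, x, y, type.
#' @return data.frame.
#' @export
read_spatial_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: spatial CSV missing column(s) ",
                         paste(miss, collapse = ", "))
  df
}

#' Read spot deconvolution weights CSV
#' @param path CSV with spot_id, x, y, then one column per type.
#' @return list(weights matrix, coords data.frame).
#' @export
read_spot_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("spot_id", "x", "y"), names(df))
  if (length(miss)) stop("schema error: spot weights CSV missing column(s) ",
                         paste(miss, collapse = ", "))
  w <- as.matrix(df[, setdiff(names(df), c("spot_id", "x", "y")), drop = FALSE])
  rownames(w) <- df$spot_id
  list(weights = w, coords = df[, c("spot_id", "x", "y")])
}

#' Read a ligand-receptor database CSV
#' @param path CSV with ligand, receptor (";"-separated subunits), pathway.
#' @return data.frame.
#' @export
read_lr_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("ligand", "receptor", "pathway"), names(df))
  if (length(miss)) stop("schema error: LR database missing column(s) ",
                         paste(miss, collapse = ", "))
  blank <- function(x) any(is.na(x) | !nzchar(as.character(x)))
  if (blank(df$ligand) || blank(df$receptor) || blank(df$pathway))
    stop("schema error: LR database has empty ligand/receptor/pathway values")
  df
}
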