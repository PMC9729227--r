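#' Write an ROI table as TSV
#'
#' Columns id, hemisphere, n_voxels, x, y, z, mean_r (centre-of-gravity
#' world coordinates in mm).
#'
#' @param rois a `roi_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  utils::write.table(rois$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a square matrix as TSV with a node-id header
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  invisible(path)
}

#' Write ground-truth metadata as JSON
#' @param gt a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(list(
    nodes = gt$nodes, edges = gt$edges,
    params = gt$params[setdiff(names(gt$params), c("nodes", "edges"))],
    seed = gt$seed), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' Recognised keys mirror the arguments of [cohort_config()]; `nodes` and
#' `edges` may be given as lists of records.
#'
#' @param path YAML file path.
#' @return a configuration list.
#' @export
read_cohort_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("shape", "voxel_mm", "n_subjects", "n_timepoints", "noise_sd",
              "signal_weight", "warp_amplitude_mm", "warp_smoothness_mm"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$nodes))
    args$nodes <- do.call(rbind, lapply(y$nodes, as.data.frame))
  if (!is.null(y$edges))
    args$edges <- do.call(rbind, lapply(y$edges, as.data.frame))
  do.call(cohort_config, args)
}

# Internal: stage-tagged logging to stderr.
log_stage <- function(stage, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}
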