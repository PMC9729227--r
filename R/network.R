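#' Select streamlines crossing at least `min_rois` ROIs
#'
#' A streamline's traversed voxel set is computed by resampling the polyline
#' at steps of half the minimum voxel dimension and mapping sample points to
#' voxels; it is retained iff it intersects at least `min_rois` distinct ROI
#' labels. Vertices outside the grid are clipped (not fatal).
#'
#' @param ss a `streamline_set` with a usable reference geometry.
#' @param roi_labels integer-label `volume_grid` of ROIs (0 = background).
#' @param min_rois minimum number of distinct ROIs crossed (default 2).
#' @return list with `selected` (a `streamline_set`), `hits` (list of integer
#'   ROI-label vectors, one per retained streamline), and `index` (positions
#'   of retained streamlines in the input).
#' @export
select_streamlines <- function(ss, roi_labels, min_rois = 2L) {
  if (!length(unique(roi_labels$data[roi_labels$data > 0])))
    stop("roi_labels contains no ROIs")
  dim3 <- dim(roi_labels$data)
  affine <- roi_labels$affine
  labvec <- as.integer(roi_labels$data)
  hits_all <- lapply(ss$streamlines, function(m) {
    vox <- streamline_voxels(m, dim3, affine)
    h <- unique(labvec[vox])
    sort(h[h > 0])
  })
  keep <- which(vapply(hits_all, length, integer(1)) >= min_rois)
  list(selected = streamline_set(ss$streamlines[keep],
                                 list(dim = dim3, affine = affine)),
       hits = hits_all[keep],
       index = keep)
}

#' Streamline density map
#'
#' Integer count of distinct streamlines traversing each voxel (each
#' streamline counts once per voxel).
#'
#' @param ss a `streamline_set`.
#' @param geometry a `volume_grid` defining the output grid (defaults to the
#'   set's reference).
#' @return an integer `volume_grid`.
#' @export
density_map <- function(ss, geometry = NULL) {
  if (is.null(geometry)) {
    if (is.null(ss$reference$dim)) stop("no reference geometry available")
    dim3 <- ss$reference$dim; affine <- ss$reference$affine
  } else {
    dim3 <- dim(geometry$data); affine <- geometry$affine
  }
  counts <- integer(prod(dim3))
  for (m in ss$streamlines) {
    vox <- streamline_voxels(m, dim3, affine)
    counts[vox] <- counts[vox] + 1L
  }
  volume_grid(array(counts, dim = dim3), affine)
}

#' Binarize a density map
#' @param vol a `volume_grid`; positive voxels become 1.
#' @return an integer 0/1 `volume_grid`.
#' @export
binarize_map <- function(vol) {
  volume_grid(array(as.integer(vol$data > 0), dim = dim(vol$data)), vol$affine)
}

#' Group-level overlap of binary maps
#' @param maps list of 0/1 `volume_grid`s with identical geometry.
#' @return a `volume_grid` of voxelwise means in \[0, 1\].
#' @export
group_overlap <- function(maps) {
  stop_unless_same_geometry(maps, "binary maps")
  shape <- dim(maps[[1]]$data)
  acc <- array(0, dim = shape)
  for (m in maps) acc <- acc + (m$data > 0)
  volume_grid(acc / length(maps), maps[[1]]$affine)
}

#' Build a structural connectome from streamline ROI-hit sets
#'
#' For each retained streamline, the count of every unordered pair of ROIs in
#' its hit set is incremented. The binary companion is `count > 0` with no
#' count threshold.
#'
#' @param hits list of integer ROI-id vectors (from [select_streamlines()]).
#' @param node_table data.frame with columns `id` (integer ROI label),
#'   `name`, `hemisphere`, `role`.
#' @param subject_id optional identifier.
#' @return object of class `connectome`: `nodes`, `structural_count`,
#'   `binary`, `subject_id`.
#' @export
connectome_from_hits <- function(hits, node_table, subject_id = NULL) {
  ids <- node_table$id
  K <- length(ids)
  counts <- matrix(0L, K, K, dimnames = list(node_table$name, node_table$name))
  for (h in hits) {
    pos <- match(h, ids)
    if (anyNA(pos))
      stop("unknown ROI id(s) in hit set: ",
           paste(h[is.na(pos)], collapse = ", "))
    if (length(pos) < 2L) next
    pr <- utils::combn(sort(pos), 2L)
    for (c2 in seq_len(ncol(pr))) {
      i <- pr[1, c2]; j <- pr[2, c2]
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[j, i] + 1L
    }
  }
  diag(counts) <- 0L
  structure(list(nodes = node_table, structural_count = counts,
                 binary = (counts > 0) * 1L, subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$nodes), " nodes, ",
      sum(x$binary) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Hub metrics across a cohort of connectomes
#'
#' Per-subject degree centrality (`degree / (N - 1)`) and betweenness
#' centrality (normalized by `2 / ((N - 1)(N - 2))`) on the undirected
#' binary graph, aggregated as the per-node median across subjects.
#'
#' @param connectomes list of `connectome`s with consistent node tables.
#' @return object of class `hub_metrics`: data.frame with `node`,
#'   `median_degree`, `median_betweenness`, plus per-subject matrices.
#' @export
hub_metrics <- function(connectomes) {
  if (!length(connectomes)) stop("need >= 1 connectome")
  nodes <- connectomes[[1]]$nodes
  N <- nrow(nodes)
  if (N < 3L) stop("betweenness centrality undefined for fewer than 3 nodes")
  deg <- bet <- matrix(NA_real_, length(connectomes), N,
                       dimnames = list(NULL, nodes$name))
  for (s in seq_along(connectomes)) {
    cn <- connectomes[[s]]
    if (!identical(cn$nodes$id, nodes$id))
      stop("connectome ", s, " has an inconsistent node table")
    g <- igraph::graph_from_adjacency_matrix(cn$binary, mode = "undirected",
                                             diag = FALSE)
    deg[s, ] <- igraph::degree(g) / (N - 1)
    bet[s, ] <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  }
  structure(list(
    table = data.frame(node = nodes$name,
                       hemisphere = nodes$hemisphere,
                       role = nodes$role,
                       median_degree = apply(deg, 2, median),
                       median_betweenness = apply(bet, 2, median),
                       stringsAsFactors = FALSE),
    degree = deg, betweenness = bet
  ), class = "hub_metrics")
}

#' @export
print.hub_metrics <- function(x, ...) {
  print(x$table[order(-x$table$median_betweenness), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Paired left-right lateralization test
#'
#' Shapiro-Wilk on the paired differences (alpha 0.05) selects a paired
#' t-test (normal) or Wilcoxon signed-rank test (otherwise). The report
#' carries mean (sd) or median \[IQR\] summaries to match the chosen test.
#'
#' @param left,right paired per-subject measures (n >= 6).
#' @param kind label recorded in the report (`"structural_volume"` or
#'   `"functional_mean"`).
#' @return list with `test`, `p`, `direction`, `summary_left`,
#'   `summary_right`, `degenerate`.
#' @export
lateralization_test <- function(left, right, kind = "structural_volume") {
  if (length(left) != length(right)) stop("left and right must be paired")
  n <- length(left)
  if (n < 6L) stop("need >= 6 paired observations")
  d <- right - left
  if (sd(d) == 0) {
    return(list(kind = kind, test = "none", p = NA_real_,
                direction = "degenerate (zero-variance differences)",
                summary_left = mean(left), summary_right = mean(right),
                degenerate = TRUE))
  }
  normal <- shapiro.test(d)$p.value > 0.05
  if (normal) {
    ht <- t.test(right, left, paired = TRUE)
    sm <- function(x) sprintf("%.3f (%.3f)", mean(x), sd(x))
    test <- "paired t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(right, left, paired = TRUE))
    sm <- function(x) sprintf("%.3f [%.3f, %.3f]", median(x),
                              quantile(x, 0.25), quantile(x, 0.75))
    test <- "Wilcoxon signed-rank"
  }
  list(kind = kind, test = test, p = ht$p.value,
       direction = if (median(d) > 0) "right > left"
                   else if (median(d) < 0) "left > right" else "none",
       summary_left = sm(left), summary_right = sm(right),
       degenerate = FALSE)
}

#' Hemispheric tract volume
#'
#' Volume (cm^3) of the density map of streamlines connecting at least two
#' distinct same-hemisphere nodes, the structural lateralization measure.
#' Midline ROIs are excluded from hemispheric sets.
#'
#' @param ss a `streamline_set`.
#' @param roi_labels integer-label `volume_grid`.
#' @param roi_table data.frame with `id` and `hemisphere` columns.
#' @param hemisphere `"L"` or `"R"`.
#' @return tract volume in cm^3.
#' @export
hemispheric_tract_volume <- function(ss, roi_labels, roi_table, hemisphere) {
  ids <- roi_table$id[roi_table$hemisphere == hemisphere]
  sel <- select_streamlines(ss, roi_labels, min_rois = 2L)
  keep <- vapply(sel$hits, function(h) sum(h %in% ids) >= 2L, logical(1))
  if (!any(keep)) return(0)
  sub <- streamline_set(sel$selected$streamlines[keep],
                        list(dim = dim(roi_labels$data),
                             affine = roi_labels$affine))
  dm <- density_map(sub)
  sum(dm$data > 0) * prod(voxel_size(roi_labels)) / 1000
}
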