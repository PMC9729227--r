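#' Seed-based correlation map
#'
#' Pearson correlation between the spatial-mean time series of a seed region
#' and every voxel's time series. Voxels with zero temporal variance map to
#' r = 0 (not NA), keeping downstream medians and statistics total.
#'
#' @param bold a `bold_series` (>= 30 timepoints).
#' @param seed_mask an integer-label `volume_grid` in the same space.
#' @param seed_id label value of the seed region.
#' @return a `volume_grid` of Pearson r in \[-1, 1\].
#' @export
seed_correlation_map <- function(bold, seed_mask, seed_id) {
  d <- dim(bold$data)
  if (d[4] < 30L) stop("bold must have >= 30 timepoints")
  if (!identical(d[1:3], dim(seed_mask$data)))
    stop("bold and seed mask grids differ")
  sel <- which(seed_mask$data == seed_id)
  if (!length(sel)) stop("seed '", seed_id, "' has no voxels")
  X <- bold_matrix(bold)
  s <- colMeans(X[sel, , drop = FALSE])
  sc <- s - mean(s)
  ss <- sqrt(sum(sc^2))
  Xc <- X - rowMeans(X)
  denom <- sqrt(rowSums(Xc^2)) * ss
  num <- as.numeric(Xc %*% sc)
  r <- ifelse(denom > 0, num / denom, 0)
  r <- pmin(1, pmax(-1, r))
  volume_grid(array(r, dim = d[1:3]), bold$affine,
              meta = list(seed_id = seed_id))
}

#' Voxelwise median of seed correlation maps
#'
#' The per-network representative map: voxelwise median over the seed maps
#' (even counts average the two central order statistics), chosen over the
#' mean for robustness to outlying seeds.
#'
#' @param seed_maps list of `volume_grid`s with identical geometry.
#' @param network optional network tag ("A"/"B") recorded in metadata.
#' @return a `volume_grid`.
#' @export
median_network_map <- function(seed_maps, network = NULL) {
  if (!length(seed_maps)) stop("need >= 1 seed map")
  stop_unless_same_geometry(seed_maps, "seed maps")
  shape <- dim(seed_maps[[1]]$data)
  m <- vapply(seed_maps, function(x) as.numeric(x$data), numeric(prod(shape)))
  med <- cpp_row_medians(matrix(m, nrow = prod(shape)))
  volume_grid(array(med, dim = shape), seed_maps[[1]]$affine,
              meta = list(network = network, n_seeds = length(seed_maps)))
}

# Internal: Ledoit-Wolf analytic shrinkage of the sample covariance toward
# the scaled identity. Returns the shrunk covariance and the intensity.
ledoit_wolf_cov <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  b2bar <- 0
  for (k in seq_len(n)) {
    xk <- Xc[k, ]
    b2bar <- b2bar + sum((tcrossprod(xk) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  rho <- if (d2 > 0) b2 / d2 else 0
  list(sigma = (1 - rho) * S + rho * diag(mu, p), shrinkage = rho)
}

#' Partial correlation matrix of node time series
#'
#' Partial correlations from the precision matrix P of the (optionally
#' shrinkage-regularised) covariance: `pc_ij = -P_ij / sqrt(P_ii P_jj)`, with
#' unit diagonal. The default Ledoit-Wolf shrinkage toward the scaled
#' identity keeps the estimate well-conditioned; `shrinkage = "none"` inverts
#' the raw sample covariance (used by analytic oracles).
#'
#' @param node_series timepoints x nodes numeric matrix (colnames = node ids).
#' @param shrinkage `"ledoit-wolf"` or `"none"`.
#' @return object of class `functional_matrix`: list with `node_ids`,
#'   `matrix`, and `shrinkage`.
#' @export
partial_correlation_matrix <- function(node_series,
                                       shrinkage = c("ledoit-wolf", "none")) {
  shrinkage <- match.arg(shrinkage)
  X <- as.matrix(node_series)
  p <- ncol(X)
  if (p < 2L) stop("need >= 2 nodes")
  if (nrow(X) <= 2L) stop("need > 2 timepoints")
  if (shrinkage == "ledoit-wolf") {
    lw <- ledoit_wolf_cov(X)
    sigma <- lw$sigma; rho <- lw$shrinkage
  } else {
    sigma <- cov(X); rho <- 0
  }
  P <- tryCatch(solve(sigma), error = function(e)
    stop("covariance is singular; too few timepoints for a positive-definite ",
         "estimate (", conditionMessage(e), ")"))
  dg <- sqrt(diag(P))
  pc <- -P / tcrossprod(dg)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  pc <- pmin(pmax(pc, -1), 1)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("node", seq_len(p))
  dimnames(pc) <- list(ids, ids)
  structure(list(node_ids = ids, matrix = pc, shrinkage = rho),
            class = "functional_matrix")
}

#' Mean correlation over one hemisphere's nodes
#'
#' Mean of a network map over the union of the voxels of that hemisphere's
#' node ROIs.
#'
#' @param nmap a `volume_grid` (e.g. a median network map).
#' @param roi_labels integer-label `volume_grid` of node ROIs.
#' @param roi_table data.frame with columns `id` (label value) and
#'   `hemisphere` ("L"/"R"/"midline").
#' @param hemisphere `"L"` or `"R"`.
#' @return mean correlation (scalar).
#' @export
hemisphere_mean_correlation <- function(nmap, roi_labels, roi_table, hemisphere) {
  ids <- roi_table$id[roi_table$hemisphere == hemisphere]
  if (!length(ids)) stop("no nodes in hemisphere '", hemisphere, "'")
  sel <- which(roi_labels$data %in% ids)
  if (!length(sel)) stop("hemisphere '", hemisphere, "' nodes cover no voxels")
  mean(nmap$data[sel])
}
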