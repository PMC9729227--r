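#' Structural projection map of a set of nuclei
#'
#' Density map of the streamlines that cross at least one nucleus ROI and at
#' least one *other* node of the network.
#'
#' @param ss a `streamline_set`.
#' @param roi_labels integer-label `volume_grid` of all network node ROIs.
#' @param nuclei_ids ROI label values of the nuclei of interest (non-empty,
#'   subset of `network_ids`).
#' @param network_ids ROI label values of all network nodes.
#' @return a `volume_grid` density map.
#' @export
projection_map <- function(ss, roi_labels, nuclei_ids, network_ids) {
  if (!length(nuclei_ids)) stop("nuclei set must be non-empty")
  if (!all(nuclei_ids %in% network_ids))
    stop("nuclei ids must be a subset of the network node ids")
  other <- setdiff(network_ids, nuclei_ids)
  sel <- select_streamlines(ss, roi_labels, min_rois = 2L)
  keep <- vapply(sel$hits, function(h)
    any(h %in% nuclei_ids) && any(h %in% other), logical(1))
  sub <- streamline_set(sel$selected$streamlines[keep],
                        list(dim = dim(roi_labels$data),
                             affine = roi_labels$affine))
  density_map(sub)
}

#' Parcellate a map
#'
#' Per-parcel mean of map values; parcel centroids are the mean world
#' coordinates of parcel voxels. Empty parcels are excluded with a warning.
#'
#' @param map a `volume_grid`.
#' @param parcellation integer-label `volume_grid` aligned with `map`.
#' @return object of class `parcel_vector`: data.frame with `id`, `value`,
#'   `x`, `y`, `z`.
#' @export
parcellate <- function(map, parcellation) {
  if (!same_geometry(map, parcellation))
    stop("map and parcellation geometry differ")
  lab <- as.integer(parcellation$data)
  all_ids <- sort(unique(lab[lab > 0]))
  vals <- tapply(as.numeric(map$data)[lab > 0], lab[lab > 0], mean)
  shape <- dim(map$data)
  idx <- arrayInd(which(lab > 0), shape) - 1
  world <- voxel_to_world(map$affine, idx)
  cen <- apply(world, 2, function(col) tapply(col, lab[lab > 0], mean))
  out <- data.frame(id = all_ids, value = as.numeric(vals),
                    x = cen[, 1], y = cen[, 2], z = cen[, 3])
  rownames(out) <- NULL
  class(out) <- c("parcel_vector", "data.frame")
  out
}

#' Spearman spatial correlation of two parcel vectors
#'
#' @param x,y `parcel_vector`s over identical parcel ids (>= 3 parcels).
#' @return Spearman's rho (ties by average ranks).
#' @export
spearman_spatial <- function(x, y) {
  if (nrow(x) < 3L) stop("need >= 3 parcels")
  if (!identical(x$id, y$id)) stop("parcel ids differ between x and y")
  cor(x$value, y$value, method = "spearman")
}

#' Cohort-level inference on per-subject spatial correlations
#'
#' Per annotation map, a one-sided Wilcoxon signed-rank test of the
#' per-subject Spearman rho distribution against zero (alternative:
#' greater), Bonferroni-corrected at `alpha / family size`. Optional paired
#' A-vs-B and L-vs-R contrasts are normality-gated (paired t or Wilcoxon)
#' and corrected at `alpha / (number of significant systems)`.
#'
#' @param rhos subjects x maps numeric matrix of Spearman correlations
#'   (colnames = map names; >= 6 subjects).
#' @param alpha family-wise alpha (default 0.05).
#' @param family_size Bonferroni family size; defaults to the number of maps.
#' @param contrast_AB optional list of two subjects x maps matrices (A, B)
#'   for the network contrast, restricted to significant systems.
#' @param contrast_LR optional list of two matrices for the hemisphere
#'   contrast.
#' @return object of class `correlation_report`.
#' @export
cohort_inference <- function(rhos, alpha = 0.05, family_size = NULL,
                             contrast_AB = NULL, contrast_LR = NULL) {
  rhos <- as.matrix(rhos)
  if (nrow(rhos) < 6L) stop("need >= 6 subjects")
  n_maps <- ncol(rhos)
  if (n_maps < 1L) stop("need >= 1 annotation map")
  if (is.null(family_size)) family_size <- n_maps
  thr <- alpha / family_size
  one_sided_p <- apply(rhos, 2, function(v) {
    if (all(v == 0)) return(1)
    wilcox.test(v, alternative = "greater", exact = FALSE)$p.value
  })
  sig <- one_sided_p < thr
  per_map <- data.frame(
    map = colnames(rhos) %||% paste0("map", seq_len(n_maps)),
    median_rho = apply(rhos, 2, median),
    iqr_lo = apply(rhos, 2, quantile, 0.25),
    iqr_hi = apply(rhos, 2, quantile, 0.75),
    wilcoxon_p = one_sided_p,
    significant = sig, stringsAsFactors = FALSE)
  rownames(per_map) <- NULL
  paired_contrast <- function(pair, thr2) {
    if (is.null(pair)) return(NULL)
    A <- as.matrix(pair[[1]]); B <- as.matrix(pair[[2]])
    data.frame(map = colnames(A) %||% paste0("map", seq_len(ncol(A))),
               p = vapply(seq_len(ncol(A)), function(j) {
                 d <- A[, j] - B[, j]
                 if (sd(d) == 0) return(1)
                 if (shapiro.test(d)$p.value > 0.05)
                   t.test(A[, j], B[, j], paired = TRUE)$p.value
                 else
                   wilcox.test(A[, j], B[, j], paired = TRUE, exact = FALSE)$p.value
               }, numeric(1)),
               threshold = thr2, stringsAsFactors = FALSE)
  }
  n_sig <- max(1L, sum(sig))
  contrast_thr <- alpha / n_sig
  structure(list(
    per_map = per_map,
    per_map_threshold = thr,
    contrast_threshold = contrast_thr,
    n_significant = sum(sig),
    contrast_AB = paired_contrast(contrast_AB, contrast_thr),
    contrast_LR = paired_contrast(contrast_LR, contrast_thr),
    alpha = alpha, family_size = family_size
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> per-map threshold ", signif(x$per_map_threshold, 3),
      " (", x$family_size, " maps), ", x$n_significant, " significant\n", sep = "")
  print(x$per_map, digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: binned empirical semivariogram over equal-count distance bins.
# When there are more than `max_pairs` parcel pairs, a fixed random subset is
# used (the estimator, not the surrogates, is subsampled).
variogram_bins <- function(centroids, n_bins, max_pairs = 20000L,
                           d_cut_quantile = 0.25) {
  D <- as.matrix(dist(centroids))
  pr <- which(upper.tri(D), arr.ind = TRUE)
  d_all <- D[pr]
  # match the short-range structure that carries the autocorrelation: only
  # pairs up to the d_cut_quantile of the distance distribution are fitted
  keep <- d_all <= quantile(d_all, d_cut_quantile)
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) > max_pairs)
    pr <- pr[sample.int(nrow(pr), max_pairs), , drop = FALSE]
  d <- D[pr]
  qs <- quantile(d, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(d, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  tab <- tabulate(bin, length(unique(qs)) - 1L)
  present <- which(tab > 0)            # drop bins emptied by subsampling
  bin <- match(bin, present)
  list(i = pr[, 1], j = pr[, 2], d = d, bin = bin,
       n_bins = length(present), counts = tab[present])
}

empirical_variogram <- function(x, vb) {
  sq <- 0.5 * (x[vb$i] - x[vb$j])^2
  as.numeric(rowsum(sq, vb$bin, reorder = TRUE)) / vb$counts
}

# Columnwise variograms of a parcels x k matrix.
empirical_variogram_mat <- function(X, vb) {
  sq <- 0.5 * (X[vb$i, , drop = FALSE] - X[vb$j, , drop = FALSE])^2
  rowsum(sq, vb$bin, reorder = TRUE) / vb$counts
}

#' Variogram-matched surrogate parcel maps
#'
#' Surrogates preserving the value distribution and (approximately) the
#' spatial autocorrelation of a parcel vector: values are randomly permuted,
#' smoothed with Gaussian distance kernels at a log-spaced grid of scales,
#' the scale and affine variogram rescaling best matching the source
#' variogram (least squares over equal-count distance bins) are selected,
#' white noise supplies the fitted nugget, and the original value multiset
#' is reassigned by rank.
#'
#' @param x a `parcel_vector` (needs centroids).
#' @param n_surrogates number of surrogates (>= 100; 5000 matches the
#'   full-scale analysis, 500 is the desk-scale default).
#' @param seed RNG seed.
#' @param n_bins distance bins for the variogram (default 25; reduced with a
#'   warning when there are fewer parcels than bins).
#' @param n_scales number of kernel scales (default 10).
#' @return object of class `surrogate_ensemble`: `values` (parcels x
#'   n_surrogates matrix), source vector, and variogram diagnostics.
#' @export
variogram_surrogates <- function(x, n_surrogates = 500L, seed = 1L,
                                 n_bins = 25L, n_scales = 10L) {
  if (n_surrogates < 100L) stop("n_surrogates must be >= 100")
  P <- nrow(x)
  if (P <= n_bins) {
    n_bins <- max(4L, P %/% 2L)
    warning("fewer parcels than distance bins; reducing to ", n_bins, " bins")
  }
  cen <- as.matrix(x[, c("x", "y", "z")])
  set.seed(seed)
  vb <- variogram_bins(cen, n_bins)
  gamma_src <- empirical_variogram(x$value, vb)
  D <- as.matrix(dist(cen))
  dpos <- D[upper.tri(D)]
  scales <- exp(seq(log(min(dpos[dpos > 0])), log(max(dpos)),
                    length.out = n_scales))
  src_sorted <- sort(x$value)
  nb <- length(gamma_src)
  # all random permutations at once (parcels x surrogates)
  Xp <- vapply(seq_len(n_surrogates), function(k) x$value[sample.int(P)],
               numeric(P))
  best_sse <- rep(Inf, n_surrogates)
  best_y <- matrix(0, P, n_surrogates)
  best_a <- best_b <- numeric(n_surrogates)
  wts <- 1 / pmax(gamma_src, 1e-12)^2
  for (si in seq_along(scales)) {
    K <- exp(-D^2 / (2 * scales[si]^2))
    K <- K / rowSums(K)
    Ys <- K %*% Xp
    GY <- empirical_variogram_mat(Ys, vb)
    # closed-form weighted least squares of gamma_src on each column
    # (slope a >= 0, intercept b >= 0); weights 1/gamma^2 make the fit
    # relative, so the short-distance bins are not sacrificed
    sw <- sum(wts)
    m_gy <- colSums(GY * wts) / sw
    m_gs <- sum(gamma_src * wts) / sw
    sxx <- colSums(wts * GY^2) - sw * m_gy^2
    sxy <- colSums(wts * GY * gamma_src) - sw * m_gy * m_gs
    a <- ifelse(sxx > 0, pmax(0, sxy / sxx), 0)
    b <- pmax(0, m_gs - a * m_gy)
    resid <- gamma_src - sweep(GY, 2, a, `*`) - rep(b, each = nb)
    sse <- colSums(wts * resid^2)
    better <- sse < best_sse
    if (any(better)) {
      best_sse[better] <- sse[better]
      best_y[, better] <- Ys[, better]
      best_a[better] <- a[better]
      best_b[better] <- b[better]
    }
  }
  Z <- sweep(best_y, 2, sqrt(best_a), `*`) +
       matrix(rnorm(P * n_surrogates), P) %*% diag(sqrt(best_b), n_surrogates)
  # rank reassignment preserves the source value multiset exactly
  out <- apply(Z, 2, function(z) src_sorted[rank(z, ties.method = "first")])
  gamma_acc <- empirical_variogram_mat(out, vb)
  structure(list(values = out, source = x$value, ids = x$id,
                 centroids = cen,
                 gamma_source = gamma_src,
                 gamma_surrogate_mean = rowMeans(gamma_acc),
                 n_surrogates = n_surrogates),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble> ", x$n_surrogates, " surrogates over ",
      length(x$source), " parcels\n", sep = "")
  invisible(x)
}

#' One-sided surrogate test of a spatial correlation
#'
#' Observed Spearman rho between `x` and `y`, compared against the
#' distribution of rho between each surrogate of `x` and `y`; upper one-sided
#' `p = (1 + #(rho_surr >= rho_obs)) / (1 + n_surrogates)`.
#'
#' @param x a `parcel_vector` (the ensemble's source map).
#' @param y a `parcel_vector` over the same parcels.
#' @param ensemble a `surrogate_ensemble` built from `x`.
#' @return list with `rho`, `p`, `null_rhos`.
#' @export
pairwise_surrogate_test <- function(x, y, ensemble) {
  if (!identical(x$id, ensemble$ids) || !identical(x$id, y$id))
    stop("ensemble/parcel mismatch between x, y and the surrogate ensemble")
  if (!isTRUE(all.equal(sort(x$value), sort(ensemble$values[, 1]))))
    stop("ensemble was not built from x (value multisets differ)")
  obs <- cor(x$value, y$value, method = "spearman")
  null_rhos <- as.numeric(cor(ensemble$values, y$value, method = "spearman"))
  p <- (1 + sum(null_rhos >= obs)) / (1 + ensemble$n_surrogates)
  list(rho = obs, p = p, null_rhos = null_rhos)
}
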