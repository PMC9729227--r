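#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over `n_steps` equal threshold
#' increments in `(0, max]`, where `e(h, v)` is the 26-connected
#' supporting-cluster extent of voxel v at height h. The negative side is
#' enhanced by applying the same transform to the negated map and negating.
#'
#' @param stat a `volume_grid` (finite values).
#' @param H height exponent (default 2).
#' @param E extent exponent (default 0.5).
#' @param n_steps number of threshold steps (>= 10, default 100).
#' @return a `volume_grid` of enhanced values.
#' @export
tfce_enhance <- function(stat, H = 2, E = 0.5, n_steps = 100L) {
  if (!all(is.finite(stat$data))) stop("stat map must be finite")
  if (H <= 0 || E <= 0) stop("H and E must be > 0")
  if (n_steps < 10L) stop("n_steps must be >= 10")
  out <- cpp_tfce(stat$data + 0, as.integer(dim(stat$data)), H, E,
                  as.integer(n_steps))
  volume_grid(array(out, dim = dim(stat$data)), stat$affine,
              meta = list(tfce = list(H = H, E = E, n_steps = n_steps)))
}

#' One-sample sign-flip permutation inference with TFCE
#'
#' Voxelwise one-sample t statistics; the null is generated by random sign
#' flips of whole subject maps; TFCE is applied to the observed and each
#' permuted t map; family-wise-error-corrected p per voxel is
#' `(1 + #(perm max-TFCE >= observed TFCE)) / (1 + n_permutations)`.
#' Zero-variance voxels get t = 0.
#'
#' @param maps list of aligned subject `volume_grid`s (>= 8 subjects).
#' @param n_permutations number of sign-flip permutations (>= 100; default
#'   5000).
#' @param seed RNG seed for the sign flips.
#' @param H,E,n_steps TFCE parameters.
#' @return object of class `stat_map` with `t_map`, `tfce_map`, `fwe_p_map`,
#'   and the permutation null `max_tfce_null`.
#' @export
one_sample_permutation <- function(maps, n_permutations = 5000L, seed = 1L,
                                   H = 2, E = 0.5, n_steps = 100L) {
  n <- length(maps)
  if (n < 8L)
    stop("refusing one-sample permutation inference with fewer than 8 ",
         "subjects: the sign-flip space is too small for FWE at 0.05")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  stop_unless_same_geometry(maps)
  shape <- dim(maps[[1]]$data)
  V <- prod(shape)
  X <- t(vapply(maps, function(m) as.numeric(m$data), numeric(V)))  # n x V
  ss <- colSums(X^2)
  t_of <- function(signs) {
    mu <- as.numeric(signs %*% X) / n
    v <- (ss - n * mu^2) / (n - 1)
    tt <- ifelse(v > 0, mu / sqrt(v / n), 0)
    tt
  }
  dims <- as.integer(shape)
  t_obs <- t_of(rep(1, n))
  tfce_obs <- cpp_tfce(t_obs, dims, H, E, as.integer(n_steps))
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  max_null <- numeric(n_permutations)
  exceed <- numeric(V)
  for (b in seq_len(n_permutations)) {
    tb <- t_of(flips[b, ])
    fb <- cpp_tfce(tb, dims, H, E, as.integer(n_steps))
    mx <- max(fb)
    max_null[b] <- mx
    exceed <- exceed + (mx >= tfce_obs)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  affine <- maps[[1]]$affine
  structure(list(
    t_map = volume_grid(array(t_obs, dim = shape), affine),
    tfce_map = volume_grid(array(tfce_obs, dim = shape), affine),
    fwe_p_map = volume_grid(array(p, dim = shape), affine),
    max_tfce_null = max_null,
    n_subjects = n, n_permutations = n_permutations,
    tfce_params = list(H = H, E = E, n_steps = n_steps)
  ), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> n = ", x$n_subjects, ", ", x$n_permutations,
      " permutations, min FWE p = ", signif(min(x$fwe_p_map$data), 3),
      "\n", sep = "")
  invisible(x)
}

# Internal: z-transform of a one-sample t map via its CDF.
z_transform_t <- function(t_arr, df) {
  z <- qnorm(pt(t_arr, df = df))
  array(pmin(pmax(z, -8.2), 8.2), dim = dim(t_arr))
}

#' Minimum-statistic conjunction of two statistical maps
#'
#' Both t maps are z-transformed; the conjunction is the voxelwise minimum of
#' the two z maps. A companion binary mask marks voxels that are FWE
#' significant in both maps.
#'
#' @param stat_A,stat_B `stat_map`s on the same grid and subject basis.
#' @param alpha FWE level for the significance mask.
#' @return list with `z_min` (a `volume_grid`) and `both_significant` (a 0/1
#'   `volume_grid`).
#' @export
conjunction_map <- function(stat_A, stat_B, alpha = 0.05) {
  if (!same_geometry(stat_A$t_map, stat_B$t_map))
    stop("statistical maps have mismatched geometry")
  zA <- z_transform_t(stat_A$t_map$data, stat_A$n_subjects - 1)
  zB <- z_transform_t(stat_B$t_map$data, stat_B$n_subjects - 1)
  zmin <- array(pmin(zA, zB), dim = dim(zA))
  mask <- (stat_A$fwe_p_map$data < alpha) & (stat_B$fwe_p_map$data < alpha)
  aff <- stat_A$t_map$affine
  list(z_min = volume_grid(zmin, aff),
       both_significant = volume_grid(array(as.numeric(mask), dim = dim(zmin)), aff))
}

#' Voxelwise difference of two group median maps
#'
#' @param median_A,median_B `volume_grid`s with identical geometry.
#' @return `median_A - median_B` as a `volume_grid`.
#' @export
difference_map <- function(median_A, median_B) {
  if (!same_geometry(median_A, median_B)) stop("geometry mismatch")
  volume_grid(median_A$data - median_B$data, median_A$affine)
}

#' Extract subcortical ROIs from a statistical map
#'
#' Selects voxels that are FWE significant (`fwe p < alpha`), exceed the
#' group-median correlation threshold (`r > r_threshold`), and lie inside the
#' subcortical mask; labels 26-connected components in scan order; assigns
#' hemisphere by the sign of the centre-of-gravity world x (x < -1 mm: L,
#' x > 1 mm: R, otherwise midline). Centres of gravity are unweighted means
#' of member-voxel world coordinates.
#'
#' @param stat a `stat_map`.
#' @param group_median_rmap group-level voxelwise-median correlation map.
#' @param subcortical_mask 0/1 `volume_grid`.
#' @param alpha FWE significance level (default 0.05).
#' @param r_threshold median-correlation threshold (default 0.1).
#' @param min_voxels minimum component size retained (default 2).
#' @return object of class `roi_set`: `labels` (int `volume_grid`) and
#'   `table` (id, hemisphere, n_voxels, x, y, z, mean_r). An empty result is
#'   a valid empty `roi_set`.
#' @export
extract_rois <- function(stat, group_median_rmap, subcortical_mask,
                         alpha = 0.05, r_threshold = 0.1, min_voxels = 2L) {
  p <- stat$fwe_p_map
  if (!same_geometry(p, group_median_rmap) || !same_geometry(p, subcortical_mask))
    stop("stat map, median map and mask must share geometry")
  sel <- (p$data < alpha) & (group_median_rmap$data > r_threshold) &
         (subcortical_mask$data > 0)
  shape <- dim(p$data)
  comp <- cpp_label_components(array(as.numeric(sel), dim = shape),
                               as.integer(shape), 0.5)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_voxels)
  lab <- array(0L, dim = shape)
  tab <- data.frame(id = integer(0), hemisphere = character(0),
                    n_voxels = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), mean_r = numeric(0),
                    stringsAsFactors = FALSE)
  for (new_id in seq_along(keep)) {
    vox <- which(comp == keep[new_id])
    lab[vox] <- new_id
    ijk <- arrayInd(vox, shape) - 1
    cog <- colMeans(voxel_to_world(p$affine, ijk))
    hemi <- if (cog[1] < -1) "L" else if (cog[1] > 1) "R" else "midline"
    tab <- rbind(tab, data.frame(
      id = new_id, hemisphere = hemi, n_voxels = length(vox),
      x = cog[1], y = cog[2], z = cog[3],
      mean_r = mean(group_median_rmap$data[vox]), stringsAsFactors = FALSE))
  }
  structure(list(labels = volume_grid(lab, p$affine), table = tab),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", nrow(x$table), " ROIs\n", sep = "")
  if (nrow(x$table)) print(x$table, digits = 3)
  invisible(x)
}
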