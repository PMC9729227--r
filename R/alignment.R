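#' Construct a warp field
#'
#' A dense displacement field parameterised (when available) by a stationary
#' velocity field, so that the exact inverse `exp(-v)` is always computable.
#' Displacements are stored in voxel units of the grid they act on.
#'
#' @param disp list of three displacement component arrays (x, y, z).
#' @param shape grid shape.
#' @param velocity optional list of three velocity component arrays.
#' @param direction `"template_to_subject"` or `"subject_to_template"`.
#' @param voxel_mm voxel size used to express displacements in mm.
#' @return object of class `warp_field` with cached `jacobian_min`.
#' @export
warp_field <- function(disp, shape, velocity = NULL,
                       direction = "template_to_subject", voxel_mm = 1) {
  stopifnot(length(disp) == 3L)
  jac <- cpp_jacobian_det(disp[[1]], disp[[2]], disp[[3]], as.integer(shape))
  structure(list(disp = disp, vel = velocity, shape = as.integer(shape),
                 direction = direction, voxel_mm = voxel_mm,
                 jacobian_min = min(jac)),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  mx <- max(sqrt(x$disp[[1]]^2 + x$disp[[2]]^2 + x$disp[[3]]^2))
  cat("<warp_field> ", paste(x$shape, collapse = " x "),
      ", max |d| = ", signif(mx, 3), " voxels, min |J| = ",
      signif(x$jacobian_min, 3), "\n", sep = "")
  invisible(x)
}

#' Exponentiate a stationary velocity field
#'
#' Scaling-and-squaring with `n_squarings` recursive compositions, yielding a
#' diffeomorphic displacement field.
#'
#' @param vel list of three velocity component arrays (voxel units).
#' @param shape grid shape.
#' @param n_squarings number of squaring steps (default 7).
#' @param voxel_mm voxel size carried on the result.
#' @return a `warp_field`.
#' @export
exp_velocity <- function(vel, shape, n_squarings = 7L, voxel_mm = 1) {
  shape <- as.integer(shape)
  sc <- 1 / 2^n_squarings
  d <- lapply(vel, function(v) v * sc)
  for (k in seq_len(n_squarings)) {
    comp <- cpp_compose_disp(d[[1]], d[[2]], d[[3]], d[[1]], d[[2]], d[[3]], shape)
    d <- list(comp$dx, comp$dy, comp$dz)
  }
  warp_field(d, shape, velocity = vel, voxel_mm = voxel_mm)
}

#' Invert a warp field
#'
#' Exact for velocity-parameterised warps (`exp(-v)`).
#'
#' @param warp a `warp_field` carrying a velocity field.
#' @return the inverse `warp_field`.
#' @export
invert_warp <- function(warp) {
  if (is.null(warp$vel))
    stop("warp has no velocity parameterisation; cannot invert exactly")
  inv <- exp_velocity(lapply(warp$vel, function(v) -v), warp$shape,
                      voxel_mm = warp$voxel_mm)
  inv$direction <- if (identical(warp$direction, "template_to_subject"))
    "subject_to_template" else "template_to_subject"
  inv
}

#' Resample a volume through a warp field
#'
#' Pull-back resampling: `out(x) = map(x + d(x))`. Real-valued maps use
#' trilinear interpolation; label volumes must use nearest-neighbour.
#'
#' @param map a `volume_grid`.
#' @param warp a `warp_field` on the same grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return the resampled `volume_grid`.
#' @export
apply_warp <- function(map, warp, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  shape <- dim(map$data)
  if (!all(shape == warp$shape)) stop("map and warp grids differ")
  if (is.integer(map$data) && interpolation == "linear")
    stop("linear interpolation of an integer label volume is not allowed; ",
         "use interpolation = 'nearest'")
  out <- cpp_warp_image(map$data + 0, as.integer(shape), warp$disp[[1]],
                        warp$disp[[2]], warp$disp[[3]],
                        as.integer(interpolation == "nearest"))
  if (is.integer(map$data)) storage.mode(out) <- "integer"
  volume_grid(out, map$affine, meta = map$meta)
}

# --- internal registration helpers ----------------------------------------

downsample_volume <- function(arr, shape, factor) {
  if (factor == 1L) return(list(arr = arr, shape = shape))
  sm <- cpp_smooth3(arr, shape, factor / 2)
  dim(sm) <- shape
  idx <- lapply(shape, function(n) seq(1L, n, by = factor))
  out <- sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  list(arr = out, shape = dim(out))
}

upsample_velocity <- function(vel, from_shape, to_shape, factor) {
  idx <- arrayInd(seq_len(prod(to_shape)), to_shape) - 1
  pts <- idx / factor
  lapply(vel, function(v) {
    array(cpp_sample3(v, as.integer(from_shape), pts, 0L) * factor,
          dim = to_shape)
  })
}

# Local statistics over a cubic window; returns locally standardized images
# and the local correlation field.
local_cc_stats <- function(f, m, shape, radius = 2L, eps = 1e-5) {
  mf <- cpp_box_mean3(f, shape, radius)
  mm <- cpp_box_mean3(m, shape, radius)
  vf <- cpp_box_mean3(f * f, shape, radius) - mf^2
  vm <- cpp_box_mean3(m * m, shape, radius) - mm^2
  cv <- cpp_box_mean3(f * m, shape, radius) - mf * mm
  vf[vf < 0] <- 0; vm[vm < 0] <- 0
  fa <- (f - mf) / sqrt(vf + eps)
  ma <- (m - mm) / sqrt(vm + eps)
  lcc <- cv / sqrt(vf * vm + eps)
  # score only where the fixed image has appreciable structure, otherwise the
  # flat background swamps the mean
  act <- vf > 1e-4 * max(vf)
  sim <- if (any(act)) mean(lcc[act]) else 0
  # force weight: local signal strength, so flat/noise-only regions do not
  # drive the deformation even after local standardization
  wgt <- sqrt(vf * vm)
  mw <- max(wgt)
  if (mw > 0) wgt <- wgt / mw
  list(fa = fa, ma = ma, lcc = lcc, sim = sim, weight = wgt)
}

gradient3 <- function(arr, shape) {
  dim(arr) <- shape
  g <- list()
  for (ax in 1:3) {
    up <- arr; dn <- arr
    n <- shape[ax]
    if (ax == 1) { up[] <- arr[c(2:n, n), , ]; dn[] <- arr[c(1, 1:(n - 1)), , ] }
    if (ax == 2) { up[] <- arr[, c(2:n, n), ]; dn[] <- arr[, c(1, 1:(n - 1)), ] }
    if (ax == 3) { up[] <- arr[, , c(2:n, n)]; dn[] <- arr[, , c(1, 1:(n - 1))] }
    g[[ax]] <- (up - dn) / 2
  }
  g
}

#' Register one map to another (diffeomorphic demons)
#'
#' Multi-resolution gradient ascent on local normalized cross-correlation
#' (cubic window, radius 2 voxels) over a stationary velocity field,
#' exponentiated by scaling-and-squaring. Updates and the velocity field are
#' Gaussian-smoothed; steps that would break Jacobian positivity are halved
#' (error after 5 halvings). Divergence at the finest level (similarity
#' decreasing for 3 consecutive accepted steps) returns the best-so-far warp
#' with a warning flag in `$flags`.
#'
#' @param moving,fixed `volume_grid`s with identical geometry.
#' @param factors multi-resolution downsampling factors (coarse to fine).
#' @param iters_per_level iterations at each level.
#' @param smooth_update Gaussian sigma (voxels) applied to each update.
#' @param smooth_field Gaussian sigma (voxels) applied to the velocity field.
#' @param step maximum update magnitude (voxels) per iteration.
#' @return a `warp_field` (direction fixed-to-moving pull-back: resampling the
#'   moving map through it aligns it to `fixed`), with `$similarity` (final
#'   mean local correlation) and `$flags` attached.
#' @export
register_pair <- function(moving, fixed, factors = c(4L, 2L, 1L),
                          iters_per_level = c(30L, 20L, 10L),
                          smooth_update = 1.5, smooth_field = 1.0,
                          step = 1.2) {
  if (!same_geometry(moving, fixed)) stop("moving and fixed geometry differ")
  if (!all(is.finite(moving$data)) || !all(is.finite(fixed$data)))
    stop("maps must be finite")
  full_shape <- as.integer(dim(fixed$data))
  vel <- NULL
  prev_shape <- NULL
  flags <- character(0)
  sim_final <- NA_real_
  for (lev in seq_along(factors)) {
    f <- factors[lev]
    fx <- downsample_volume(fixed$data + 0, full_shape, f)
    mv <- downsample_volume(moving$data + 0, full_shape, f)
    shape <- as.integer(fx$shape)
    if (is.null(vel)) {
      vel <- lapply(1:3, function(i) array(0, dim = shape))
    } else {
      vel <- upsample_velocity(vel, prev_shape, shape, factors[lev - 1] / f)
    }
    finest <- lev == length(factors)
    best_vel <- vel
    best_sim <- -Inf
    decreasing <- 0L
    sim_prev <- -Inf
    for (it in seq_len(iters_per_level[lev])) {
      w <- exp_velocity(vel, shape)
      mw <- cpp_warp_image(mv$arr, shape, w$disp[[1]], w$disp[[2]], w$disp[[3]], 0L)
      st <- local_cc_stats(fx$arr, mw, shape)
      sim <- st$sim
      if (sim > best_sim) { best_sim <- sim; best_vel <- vel }
      if (finest) {
        if (sim < sim_prev - 1e-4) decreasing <- decreasing + 1L
        else decreasing <- 0L
        if (decreasing >= 3L) {
          flags <- c(flags, "diverged")
          log_stage("align", "similarity plateau at finest level; ",
                    "keeping best-so-far warp", verbose = FALSE)
          break
        }
        sim_prev <- sim
      }
      diffim <- (st$fa - st$ma) * st$weight
      g <- gradient3(st$ma, shape)
      upd <- lapply(g, function(gc) cpp_smooth3(diffim * gc, shape, smooth_update))
      mx <- sqrt(max(upd[[1]]^2 + upd[[2]]^2 + upd[[3]]^2))
      if (mx < 1e-12) break
      sc <- step / mx
      ok <- FALSE
      for (halve in 0:5) {
        cand <- lapply(1:3, function(i)
          cpp_smooth3(vel[[i]] + upd[[i]] * sc, shape, smooth_field))
        cand <- lapply(cand, function(v) array(v, dim = shape))
        wc <- exp_velocity(cand, shape)
        if (wc$jacobian_min > 0) { ok <- TRUE; vel <- cand; break }
        sc <- sc / 2
      }
      if (!ok) stop("registration step broke Jacobian positivity after 5 halvings")
    }
    vel <- best_vel
    sim_final <- best_sim
    prev_shape <- shape
  }
  out <- exp_velocity(vel, full_shape)
  out$direction <- "fixed_to_moving"
  out$similarity <- sim_final
  out$flags <- flags
  out
}

#' Build an unbiased groupwise template from correlation maps
#'
#' Iteration 0 seeds the template with the voxelwise mean. Each iteration
#' registers every map to the current template, averages the warped maps, and
#' applies the inverse of the average warp to remove bias toward the initial
#' reference. An iteration whose mean similarity falls below the previous
#' best (beyond 1e-6) keeps the previous state, so the logged similarity is
#' non-decreasing.
#'
#' @param maps list of >= 2 `volume_grid`s with identical geometry.
#' @param n_iterations number of template refinement iterations (default 4).
#' @param ... passed to [register_pair()].
#' @return object of class `functional_template` with `template_map`,
#'   per-subject `warps`, warped maps, and `iteration_log`.
#' @export
build_template <- function(maps, n_iterations = 4L, ...) {
  if (length(maps) < 2L) stop("need >= 2 maps")
  stop_unless_same_geometry(maps)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  shape <- as.integer(dim(maps[[1]]$data))
  affine <- maps[[1]]$affine
  stack <- vapply(maps, function(m) as.numeric(m$data), numeric(prod(shape)))
  template <- array(rowMeans(stack), dim = shape)
  state <- list(template = template, warps = NULL, warped = NULL, sim = -Inf)
  log_sim <- numeric(0)
  for (iter in seq_len(n_iterations)) {
    tmpl_vg <- volume_grid(state$template, affine)
    warps <- lapply(maps, function(m) register_pair(m, tmpl_vg, ...))
    warped <- lapply(seq_along(maps), function(i)
      apply_warp(maps[[i]], warps[[i]], "linear"))
    sim <- mean(vapply(warps, function(w) w$similarity, numeric(1)))
    if (sim < state$sim - 1e-6) {
      log_sim <- c(log_sim, state$sim)   # keep previous state
      next
    }
    wstack <- vapply(warped, function(m) as.numeric(m$data), numeric(prod(shape)))
    new_t <- array(rowMeans(wstack), dim = shape)
    mean_vel <- lapply(1:3, function(c3) {
      acc <- array(0, dim = shape)
      for (w in warps) acc <- acc + w$vel[[c3]]
      acc / length(warps)
    })
    unbias <- exp_velocity(lapply(mean_vel, function(v) -v), shape)
    new_t <- cpp_warp_image(new_t, shape, unbias$disp[[1]], unbias$disp[[2]],
                            unbias$disp[[3]], 0L)
    state <- list(template = array(new_t, dim = shape), warps = warps,
                  warped = warped, sim = sim)
    log_sim <- c(log_sim, sim)
  }
  structure(list(
    template_map = volume_grid(state$template, affine),
    warps = state$warps,
    warped_maps = state$warped,
    iteration_log = log_sim
  ), class = "functional_template")
}

#' @export
print.functional_template <- function(x, ...) {
  cat("<functional_template> ", length(x$warps), " subjects, ",
      length(x$iteration_log), " iterations, final similarity ",
      signif(x$iteration_log[length(x$iteration_log)], 4), "\n", sep = "")
  invisible(x)
}
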