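#' Default synthetic cohort configuration
#'
#' Desk-scale study conditions: 20 subjects on a 32 x 38 x 32 grid of 2 mm
#' isotropic voxels, 120 timepoints, BOLD noise sd 1, signal weight 0.7, warp
#' amplitude 3 mm with 8 mm smoothness. Two cortical networks (A and B, four
#' nodes per hemisphere each) share four subcortical nodes; one subcortical
#' node (`thal_R`) is planted as the structural hub, and same-hemisphere
#' right edges carry 20% heavier streamline counts so that structural
#' connectivity is right-lateralized.
#'
#' @param shape grid shape (>= 24 per axis).
#' @param voxel_mm isotropic voxel size in mm.
#' @param n_subjects default cohort size.
#' @param n_timepoints BOLD timepoints per subject (>= 30).
#' @param noise_sd BOLD noise standard deviation (sigma > 0).
#' @param signal_weight latent signal weight w.
#' @param warp_amplitude_mm maximum random warp displacement (mm); 0 disables.
#' @param warp_smoothness_mm Gaussian smoothness of the random velocity field.
#' @param nodes node definition table (see [default_nodes()]).
#' @param edges ground-truth structural edge table (from, to, count).
#' @return a named list of configuration values.
#' @export
cohort_config <- function(shape = c(32L, 38L, 32L), voxel_mm = 2,
                          n_subjects = 20L, n_timepoints = 120L,
                          noise_sd = 1, signal_weight = 0.7,
                          warp_amplitude_mm = 3, warp_smoothness_mm = 8,
                          nodes = default_nodes(), edges = default_edges()) {
  list(shape = as.integer(shape), voxel_mm = voxel_mm,
       n_subjects = as.integer(n_subjects), n_timepoints = as.integer(n_timepoints),
       noise_sd = noise_sd, signal_weight = signal_weight,
       warp_amplitude_mm = warp_amplitude_mm,
       warp_smoothness_mm = warp_smoothness_mm,
       nodes = nodes, edges = edges)
}

#' Default node table of the synthetic template
#'
#' Eight cortical nodes per network (four per hemisphere) arranged on lateral
#' shells, plus four shared subcortical nodes (two thalamus-like, two
#' brainstem-like, one of each per hemisphere). World x < 0 is the left
#' hemisphere.
#'
#' @return data.frame with columns id, role, hemisphere, x, y, z, radius_mm,
#'   net_A, net_B.
#' @export
default_nodes <- function() {
  ang_A <- c(0, 90, 180, 270) * pi / 180
  ang_B <- c(45, 135, 225, 315) * pi / 180
  cort <- function(net, hemi, ang) {
    x <- if (hemi == "L") -20 else 20
    data.frame(id = paste0(net, "_", hemi, seq_along(ang)),
               role = paste0("cortical_", net), hemisphere = hemi,
               x = x, y = round(24 * cos(ang), 1), z = round(24 * sin(ang), 1),
               radius_mm = 4, net_A = net == "A", net_B = net == "B",
               stringsAsFactors = FALSE)
  }
  sub <- data.frame(
    id = c("thal_L", "thal_R", "bs_L", "bs_R"),
    role = "subcortical_shared",
    hemisphere = c("L", "R", "L", "R"),
    x = c(-8, 8, -4, 4), y = c(-6, -6, -16, -16), z = c(4, 4, -14, -14),
    radius_mm = 3.5, net_A = TRUE, net_B = TRUE, stringsAsFactors = FALSE)
  rbind(cort("A", "L", ang_A), cort("A", "R", ang_A),
        cort("B", "L", ang_B), cort("B", "R", ang_B), sub)
}

#' Default ground-truth structural edge table
#'
#' Within-network chains in each hemisphere, two interhemispheric callosal
#' edges, symmetric cortico-subcortical and subcortico-subcortical edges, and
#' four extra bridging edges on the planted hub (`thal_R`). Same-hemisphere
#' right edges carry counts inflated by 1.2.
#'
#' @return data.frame with columns from, to, count.
#' @export
default_edges <- function() {
  base <- 10L
  e <- function(a, b, right_lateral = FALSE)
    data.frame(from = a, to = b,
               count = if (right_lateral) as.integer(round(base * 1.2)) else base,
               stringsAsFactors = FALSE)
  chains <- do.call(rbind, lapply(c("A", "B"), function(net) {
    do.call(rbind, lapply(c("L", "R"), function(h) {
      ids <- paste0(net, "_", h, 1:4)
      do.call(rbind, lapply(1:3, function(i) e(ids[i], ids[i + 1], h == "R")))
    }))
  }))
  rbind(chains,
        e("A_L1", "A_R1"), e("B_L1", "B_R1"),
        e("thal_L", "A_L2"), e("thal_R", "A_R2", TRUE),
        e("bs_L", "B_L2"), e("bs_R", "B_R2", TRUE),
        e("thal_L", "bs_L"), e("thal_R", "bs_R", TRUE),
        e("thal_L", "thal_R"), e("bs_L", "bs_R"),
        e("thal_R", "A_L3"), e("thal_R", "B_L3"),
        e("thal_R", "A_R3", TRUE), e("thal_R", "B_R3", TRUE))
}

#' Study-scale cohort configuration
#'
#' A configuration whose cortical seed counts emulate the scale of the real
#' networks this pipeline targets: 23 network-A seeds (11 left, 12 right) and
#' 32 network-B seeds (19 left, 13 right), placed on lateral sunflower
#' lattices, with the default shared subcortical nodes.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a configuration list.
#' @export
study_scale_config <- function(...) {
  sunflower <- function(n, hemi, net, r_disc = 26) {
    k <- seq_len(n)
    golden <- pi * (3 - sqrt(5))
    r <- r_disc * sqrt((k - 0.5) / n)
    th <- k * golden
    x_abs <- if (net == "A") 21 else 26   # two lateral shells per hemisphere
    data.frame(id = paste0(net, "_", hemi, k),
               role = paste0("cortical_", net), hemisphere = hemi,
               x = if (hemi == "L") -x_abs else x_abs,
               y = round(r * cos(th), 2), z = round(r * sin(th) * 0.8, 2),
               radius_mm = 2.2, net_A = net == "A", net_B = net == "B",
               stringsAsFactors = FALSE)
  }
  sub <- default_nodes()
  sub <- sub[sub$role == "subcortical_shared", ]
  nodes <- rbind(sunflower(11, "L", "A"), sunflower(12, "R", "A"),
                 sunflower(19, "L", "B"), sunflower(13, "R", "B"), sub)
  edges <- data.frame(from = c("thal_L", "thal_R"), to = c("A_L1", "A_R1"),
                      count = c(5L, 6L), stringsAsFactors = FALSE)
  cohort_config(nodes = nodes, edges = edges, ...)
}

# Internal: centred axis-aligned affine (world origin at grid centre).
template_affine <- function(shape, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * voxel_mm
  aff
}

# Internal: render node spheres as an integer label volume; error on overlap.
render_node_labels <- function(nodes, shape, affine) {
  lab <- array(0L, dim = shape)
  owner <- character(prod(shape))
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1
  world <- voxel_to_world(affine, idx)
  for (k in seq_len(nrow(nodes))) {
    d2 <- (world[, 1] - nodes$x[k])^2 + (world[, 2] - nodes$y[k])^2 +
          (world[, 3] - nodes$z[k])^2
    inside <- d2 <= nodes$radius_mm[k]^2
    clash <- inside & lab > 0
    if (any(clash)) {
      other <- unique(nodes$id[lab[clash]])
      stop("node spheres overlap on the template grid: ",
           paste(unique(c(other, nodes$id[k])), collapse = ", "))
    }
    lab[inside] <- k
  }
  lab
}

#' Generate the planted ground truth of a synthetic cohort
#'
#' Renders the node spheres on the template grid, builds the per-network
#' membership masks (networks A and B share exactly the subcortical nodes),
#' and packages the structural edge table and simulation parameters.
#'
#' @param config configuration from [cohort_config()].
#' @param seed RNG seed recorded for downstream subject generation.
#' @return object of class `ground_truth`.
#' @export
generate_ground_truth <- function(config = cohort_config(), seed = 1L) {
  shape <- config$shape
  if (any(shape < 24L)) stop("template shape must be >= 24 voxels per axis")
  nodes <- config$nodes
  for (net in c("net_A", "net_B")) {
    n_cort <- sum(nodes[[net]] & nodes$role != "subcortical_shared")
    if (n_cort < 4L) stop("need >= 4 cortical nodes per network")
  }
  subc <- nodes[nodes$role == "subcortical_shared", ]
  if (!all(c("L", "R") %in% subc$hemisphere))
    stop("need at least one subcortical_shared node in each hemisphere")
  if (any(nodes$radius_mm <= 0)) stop("node radii must be > 0")
  if (config$noise_sd <= 0) stop("noise sd must be > 0")
  if (any(config$edges$count < 0)) stop("edge counts must be >= 0")
  missing_ref <- setdiff(c(config$edges$from, config$edges$to), nodes$id)
  if (length(missing_ref))
    stop("structural edges reference undefined nodes: ",
         paste(missing_ref, collapse = ", "))
  affine <- template_affine(shape, config$voxel_mm)
  lab <- render_node_labels(nodes, shape, affine)
  mem <- function(net) {
    sel <- which(nodes[[net]])
    array(as.numeric(lab %in% sel), dim = shape)
  }
  structure(list(
    nodes = nodes, edges = config$edges, params = config, seed = as.integer(seed),
    labels = volume_grid(lab, affine, meta = list(node_ids = nodes$id)),
    membership_A = volume_grid(mem("net_A"), affine),
    membership_B = volume_grid(mem("net_B"), affine)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$role == "subcortical_shared"), " subcortical), ",
      nrow(x$edges), " structural edges\n", sep = "")
  invisible(x)
}

#' Binary mask of a set of ground-truth nodes
#' @param gt a `ground_truth`.
#' @param ids node ids; defaults to all subcortical nodes.
#' @param dilate_mm radial dilation in mm (0 = exact node spheres).
#' @return a `volume_grid` with 0/1 data.
#' @export
node_mask <- function(gt, ids = NULL, dilate_mm = 0) {
  nodes <- gt$nodes
  if (is.null(ids)) ids <- nodes$id[nodes$role == "subcortical_shared"]
  sel <- nodes[nodes$id %in% ids, , drop = FALSE]
  if (!nrow(sel)) stop("no matching node ids")
  shape <- dim(gt$labels$data)
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1
  world <- voxel_to_world(gt$labels$affine, idx)
  m <- rep(FALSE, prod(shape))
  for (k in seq_len(nrow(sel))) {
    d2 <- (world[, 1] - sel$x[k])^2 + (world[, 2] - sel$y[k])^2 +
          (world[, 3] - sel$z[k])^2
    m <- m | (d2 <= (sel$radius_mm[k] + dilate_mm)^2)
  }
  volume_grid(array(as.numeric(m), dim = shape), gt$labels$affine)
}

# Internal: smooth standardized latent series (temporal Gaussian, FWHM 3
# samples).
latent_series <- function(n) {
  raw <- rnorm(n + 20L)
  sm <- cpp_smooth3(raw, c(n + 20L, 1L, 1L), 3 / (2 * sqrt(2 * log(2))))
  x <- sm[11:(n + 10L)]
  as.numeric(scale(x))
}

# Internal: random stationary velocity field scaled to a target maximum
# displacement (voxel units), returned with its exponentials.
random_velocity <- function(shape, amplitude_vox, smooth_vox) {
  v <- lapply(1:3, function(i) {
    cpp_smooth3(rnorm(prod(shape)), shape, smooth_vox)
  })
  mag <- sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
  sc <- amplitude_vox / max(mag)
  lapply(v, function(comp) array(comp * sc, dim = shape))
}

#' Generate one synthetic subject
#'
#' Draws a smooth random diffeomorphism (Gaussian-smoothed stationary velocity
#' field, exponentiated by scaling-and-squaring), warps the template node
#' labels and membership masks into subject space, synthesises BOLD as
#' `w * L_A(t) * m_A(v) + w * L_B(t) * m_B(v) + noise`, and draws jittered
#' quadratic Bezier streamlines between warped node centroids (one polyline
#' per unit of ground-truth edge count).
#'
#' @param gt a `ground_truth`.
#' @param subject_id identifier string.
#' @param n_timepoints BOLD length (>= 30); defaults to the configured value.
#' @param seed RNG seed.
#' @return object of class `subject_record` with fields `true_warp`, `bold`,
#'   `streamlines`, `seed_labels` and the generating `latents`.
#' @export
generate_subject <- function(gt, subject_id, n_timepoints = NULL, seed = 1L) {
  p <- gt$params
  if (is.null(n_timepoints)) n_timepoints <- p$n_timepoints
  if (n_timepoints < 30L) stop("n_timepoints must be >= 30")
  set.seed(seed)
  shape <- dim(gt$labels$data)
  affine <- gt$labels$affine
  vox <- p$voxel_mm
  a_vox <- p$warp_amplitude_mm / vox
  # --- diffeomorphic subject warp -----------------------------------------
  if (a_vox > 0) {
    amp <- a_vox
    warp <- NULL
    for (try in 1:5) {
      vel <- random_velocity(shape, amp, p$warp_smoothness_mm / vox)
      w <- exp_velocity(vel, shape)
      if (w$jacobian_min > 0) { warp <- w; break }
      amp <- amp * 0.7
    }
    if (is.null(warp))
      stop("could not draw an invertible warp after 5 amplitude reductions")
  } else {
    zero <- array(0, dim = shape)
    warp <- warp_field(list(zero, zero, zero), shape,
                       velocity = list(zero, zero, zero),
                       direction = "template_to_subject", voxel_mm = vox)
  }
  warp$direction <- "template_to_subject"
  d <- warp$disp
  seed_lab <- cpp_warp_image(gt$labels$data + 0, shape, d[[1]], d[[2]], d[[3]], 1L)
  storage.mode(seed_lab) <- "integer"
  mA <- cpp_warp_image(gt$membership_A$data, shape, d[[1]], d[[2]], d[[3]], 1L)
  mB <- cpp_warp_image(gt$membership_B$data, shape, d[[1]], d[[2]], d[[3]], 1L)
  # --- BOLD ----------------------------------------------------------------
  LA <- latent_series(n_timepoints)
  LB <- latent_series(n_timepoints)
  w_sig <- p$signal_weight
  V <- prod(shape)
  bold <- matrix(rnorm(V * n_timepoints, sd = p$noise_sd), V, n_timepoints)
  idxA <- which(mA > 0)
  idxB <- which(mB > 0)
  if (length(idxA)) bold[idxA, ] <- bold[idxA, ] + w_sig * rep(LA, each = length(idxA))
  if (length(idxB)) bold[idxB, ] <- bold[idxB, ] + w_sig * rep(LB, each = length(idxB))
  dim(bold) <- c(shape, n_timepoints)
  # --- streamlines ---------------------------------------------------------
  inv <- invert_warp(warp)
  centres <- as.matrix(gt$nodes[, c("x", "y", "z")])
  cen_vox <- world_to_voxel(affine, centres)
  shift <- vapply(1:3, function(c3)
    cpp_sample3(inv$disp[[c3]], shape, cen_vox, 0L), numeric(nrow(centres)))
  cen_subj <- voxel_to_world(affine, cen_vox + shift)
  rownames(cen_subj) <- gt$nodes$id
  lo <- voxel_to_world(affine, matrix(c(0, 0, 0), 1))
  hi <- voxel_to_world(affine, matrix(shape - 1, 1))
  sl <- list()
  for (k in seq_len(nrow(gt$edges))) {
    p0 <- cen_subj[gt$edges$from[k], ]
    p1 <- cen_subj[gt$edges$to[k], ]
    n_sl <- gt$edges$count[k]
    if (n_sl < 1) next
    for (j in seq_len(n_sl)) {
      ctrl <- (p0 + p1) / 2 + rnorm(3, sd = 2)
      len <- sqrt(sum((p1 - p0)^2)) * 1.1
      tt <- seq(0, 1, length.out = max(3L, ceiling(len) + 1L))
      pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) + outer(tt^2, p1)
      pts <- pmin(pmax(pts, rep(lo, each = nrow(pts))), rep(hi, each = nrow(pts)))
      sl[[length(sl) + 1L]] <- pts
    }
  }
  structure(list(
    subject_id = subject_id,
    true_warp = warp,
    bold = bold_series(bold, affine),
    streamlines = streamline_set(sl, list(dim = shape, affine = affine)),
    seed_labels = volume_grid(seed_lab, affine),
    latents = list(A = LA, B = LB),
    node_centres = cen_subj
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, ": ",
      n_timepoints(x$bold), " timepoints, ",
      length(x$streamlines), " streamlines\n", sep = "")
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' @param gt a `ground_truth`.
#' @param n_subjects number of subjects; defaults to the configured value.
#' @param seed base RNG seed; subject i uses `seed + i`.
#' @return list of `subject_record`s.
#' @export
generate_cohort <- function(gt, n_subjects = NULL, seed = 1L) {
  if (is.null(n_subjects)) n_subjects <- gt$params$n_subjects
  lapply(seq_len(n_subjects), function(i)
    generate_subject(gt, sprintf("sub-%02d", i), seed = seed + i))
}

#' Generate a synthetic annotation map with controlled spatial correlation
#'
#' Returns `rho_p * rank_normal(reference) + sqrt(1 - rho_p^2) * G`, where G
#' is a standardized Gaussian random field of the requested smoothness and
#' `rho_p = 2 sin(pi * rho_target / 6)` is the Pearson coefficient whose
#' bivariate-normal Spearman correlation equals `rho_target`.
#'
#' @param gt a `ground_truth` (supplies the grid).
#' @param reference a `volume_grid` the annotation should correlate with.
#' @param rho_target target Spearman correlation in \[-1, 1\].
#' @param smoothness_mm Gaussian smoothness of the noise field; must be 0 when
#'   `|rho_target| = 1` (an exact rank copy admits no noise field).
#' @param seed RNG seed.
#' @return a `volume_grid`.
#' @export
generate_annotation_map <- function(gt, reference, rho_target, smoothness_mm = 6,
                                    seed = 1L) {
  if (abs(rho_target) > 1) stop("rho_target must lie in [-1, 1]")
  if (!all(is.finite(reference$data))) stop("reference map must be finite")
  shape <- dim(reference$data)
  V <- prod(shape)
  z_ref <- qnorm((rank(as.vector(reference$data), ties.method = "average") - 0.5) / V)
  if (abs(rho_target) == 1) {
    if (smoothness_mm > 0)
      stop("|rho_target| = 1 is incompatible with a nonzero-smoothness noise ",
           "field; pass smoothness_mm = 0 for an exact rank copy")
    return(volume_grid(array(sign(rho_target) * z_ref, dim = shape),
                       reference$affine))
  }
  set.seed(seed)
  vox <- voxel_size(reference)[1]
  g <- cpp_smooth3(rnorm(V), shape, smoothness_mm / vox)
  # residualize the noise field against the reference so the realized
  # voxel-level correlation equals the target exactly, not just in
  # expectation (one map is one draw; an uncontrolled draw biases every
  # downstream per-subject correlation the same way)
  g <- g - mean(g)
  g <- g - sum(g * z_ref) / sum(z_ref^2) * z_ref
  g <- g / sd(g)
  rho_p <- 2 * sin(pi * rho_target / 6)
  y <- rho_p * z_ref + sqrt(1 - rho_p^2) * g
  volume_grid(array(y, dim = shape), reference$affine)
}

#' Generate a synthetic block parcellation
#'
#' Tiles the grid into cubic blocks of approximately `block_mm` edge length;
#' block indices become parcel labels (1..P).
#'
#' @param gt a `ground_truth`.
#' @param block_mm target parcel edge length in mm.
#' @return an integer-label `volume_grid`.
#' @export
generate_parcellation <- function(gt, block_mm = 8) {
  shape <- dim(gt$labels$data)
  b <- max(1L, round(block_mm / gt$params$voxel_mm))
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1
  bi <- idx %/% b
  nb <- apply(bi, 2, max) + 1
  lab <- as.integer(bi[, 1] + nb[1] * (bi[, 2] + nb[2] * bi[, 3])) + 1L
  lab <- as.integer(match(lab, sort(unique(lab))))
  volume_grid(array(lab, dim = shape), gt$labels$affine)
}
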