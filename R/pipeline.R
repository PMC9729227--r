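#' Dice coefficient of two binary masks
#' @param a,b logical/0-1 arrays or `volume_grid`s of identical shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "volume_grid")) a <- a$data
  if (inherits(b, "volume_grid")) b <- b$data
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Internal: all seed correlation maps for a subject in one pass (the BOLD
# matrix is centred once; each seed then costs one matrix-vector product).
seed_maps_all <- function(bold, seed_labels, seed_ids) {
  d <- dim(bold$data)
  X <- bold_matrix(bold)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  out <- vector("list", length(seed_ids))
  names(out) <- as.character(seed_ids)
  for (k in seq_along(seed_ids)) {
    sel <- which(seed_labels$data == seed_ids[k])
    if (!length(sel)) stop("seed '", seed_ids[k], "' has no voxels")
    s <- colMeans(X[sel, , drop = FALSE])
    sc <- s - mean(s)
    denom <- nrm * sqrt(sum(sc^2))
    r <- ifelse(denom > 0, as.numeric(Xc %*% sc) / denom, 0)
    out[[k]] <- volume_grid(array(pmin(1, pmax(-1, r)), dim = d[1:3]),
                            bold$affine, meta = list(seed_id = seed_ids[k]))
  }
  out
}

# Internal: mean pairwise Dice of per-subject binary masks.
mean_pairwise_dice <- function(masks) {
  n <- length(masks)
  acc <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- acc + dice_coefficient(masks[[i]], masks[[j]])
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort with planted ground truth and runs every stage:
#' per-seed correlation maps and per-network medians, groupwise diffeomorphic
#' alignment, sign-flip permutation inference with TFCE, conjunction and
#' difference maps, subcortical ROI extraction, streamline connectomics with
#' hub metrics, structural and functional lateralization tests, and
#' annotation-map correlation with variogram-surrogate nulls.
#'
#' @param config cohort configuration from [cohort_config()].
#' @param seed master RNG seed.
#' @param n_permutations sign-flip permutations for the group inference
#'   (desk-scale default 500; the full-scale analysis uses 5000).
#' @param n_surrogates surrogates for the annotation null (default 300).
#' @param annotation_rhos named target Spearman correlations of the three
#'   synthetic annotation maps.
#' @param template_iterations template refinement iterations (default 4).
#' @param parcel_mm parcel edge length for the annotation analysis.
#' @param verbose log stages to stderr.
#' @return a named list of results (see the package vignette).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         n_permutations = 500L, n_surrogates = 300L,
                         annotation_rhos = c(pos = 0.5, null = 0, neg = -0.3),
                         template_iterations = 4L, parcel_mm = 10,
                         verbose = TRUE) {
  t0 <- Sys.time()
  gt <- generate_ground_truth(config, seed = seed)
  log_stage("simulate", "generating ", config$n_subjects, " subjects",
            verbose = verbose)
  cohort <- generate_cohort(gt, seed = seed)
  nodes <- gt$nodes
  node_ids <- seq_len(nrow(nodes))
  subcortical_ids <- node_ids[nodes$role == "subcortical_shared"]
  cortical_A <- node_ids[nodes$net_A & nodes$role != "subcortical_shared"]
  cortical_B <- node_ids[nodes$net_B & nodes$role != "subcortical_shared"]

  # --- per-subject median network maps ------------------------------------
  log_stage("map", "seed correlation maps", verbose = verbose)
  median_maps <- list(A = list(), B = list())
  for (s in seq_along(cohort)) {
    sub <- cohort[[s]]
    smA <- seed_maps_all(sub$bold, sub$seed_labels, cortical_A)
    smB <- seed_maps_all(sub$bold, sub$seed_labels, cortical_B)
    median_maps$A[[s]] <- median_network_map(smA, network = "A")
    median_maps$B[[s]] <- median_network_map(smB, network = "B")
  }

  # --- groupwise functional alignment -------------------------------------
  log_stage("align", "building functional templates", verbose = verbose)
  tmpl <- lapply(median_maps, build_template, n_iterations = template_iterations)

  # --- group inference -----------------------------------------------------
  log_stage("infer", n_permutations, " sign-flip permutations", verbose = verbose)
  stats <- lapply(c(A = "A", B = "B"), function(net)
    one_sample_permutation(tmpl[[net]]$warped_maps,
                           n_permutations = n_permutations, seed = seed))
  group_median <- lapply(tmpl, function(tm) median_network_map(tm$warped_maps))
  conj <- conjunction_map(stats$A, stats$B)
  diffm <- difference_map(group_median$A, group_median$B)

  # --- subcortical ROI extraction ------------------------------------------
  subc_mask <- node_mask(gt, dilate_mm = 6)
  rois <- lapply(c(A = "A", B = "B"), function(net)
    extract_rois(stats[[net]], group_median[[net]], subc_mask))
  truth_mask <- node_mask(gt, dilate_mm = 0)
  recovery <- lapply(rois, function(rs) {
    hit <- vapply(subcortical_ids, function(nid) {
      tm <- gt$labels$data == nid
      any(rs$labels$data[tm] > 0)
    }, logical(1))
    names(hit) <- nodes$id[subcortical_ids]
    list(dice = dice_coefficient(rs$labels$data > 0, truth_mask$data),
         node_recovered = hit, all_recovered = all(hit))
  })

  # --- alignment gain (network A warps, subcortical masks) ------------------
  subj_subc <- lapply(cohort, function(sub)
    volume_grid(array(as.numeric(sub$seed_labels$data %in% subcortical_ids),
                      dim = dim(sub$seed_labels$data)), sub$seed_labels$affine))
  warped_subc <- lapply(seq_along(cohort), function(s)
    apply_warp(subj_subc[[s]], tmpl$A$warps[[s]], "nearest"))
  dice_unaligned <- mean_pairwise_dice(subj_subc)
  dice_aligned <- mean_pairwise_dice(warped_subc)

  # --- structural connectomics ---------------------------------------------
  log_stage("connectome", "streamline selection and graph metrics",
            verbose = verbose)
  node_table <- data.frame(id = node_ids, name = nodes$id,
                           hemisphere = nodes$hemisphere, role = nodes$role,
                           stringsAsFactors = FALSE)
  connectomes <- lapply(cohort, function(sub) {
    sel <- select_streamlines(sub$streamlines, sub$seed_labels)
    connectome_from_hits(sel$hits, node_table, subject_id = sub$subject_id)
  })
  hubs <- hub_metrics(connectomes)
  sub_tab <- hubs$table[hubs$table$role == "subcortical_shared", ]
  hub_top <- sub_tab$node[which.max(sub_tab$median_betweenness)]

  # --- lateralization ------------------------------------------------------
  log_stage("lateralize", "paired hemispheric tests", verbose = verbose)
  lat <- list()
  for (net in c("A", "B")) {
    net_nodes <- node_table[if (net == "A") nodes$net_A else nodes$net_B, ]
    vols <- vapply(cohort, function(sub) {
      c(L = hemispheric_tract_volume(sub$streamlines, sub$seed_labels,
                                     net_nodes, "L"),
        R = hemispheric_tract_volume(sub$streamlines, sub$seed_labels,
                                     net_nodes, "R"))
    }, numeric(2))
    fc <- vapply(seq_along(cohort), function(s) {
      nm <- median_maps[[net]][[s]]
      c(L = hemisphere_mean_correlation(nm, cohort[[s]]$seed_labels,
                                        net_nodes, "L"),
        R = hemisphere_mean_correlation(nm, cohort[[s]]$seed_labels,
                                        net_nodes, "R"))
    }, numeric(2))
    lat[[net]] <- list(
      structural = lateralization_test(vols["L", ], vols["R", ],
                                       kind = "structural_volume"),
      functional = lateralization_test(fc["L", ], fc["R", ],
                                       kind = "functional_mean"),
      volumes = vols, correlations = fc)
  }

  # --- annotation correlation ----------------------------------------------
  log_stage("annotate", "projection maps and surrogate nulls", verbose = verbose)
  net_A_ids <- node_ids[nodes$net_A]
  proj_subj <- lapply(seq_along(cohort), function(s) {
    pm <- projection_map(cohort[[s]]$streamlines, cohort[[s]]$seed_labels,
                         nuclei_ids = subcortical_ids, network_ids = net_A_ids)
    pm <- volume_grid(pm$data + 0, pm$affine)  # counts, not labels
    apply_warp(pm, tmpl$A$warps[[s]], "linear")
  })
  avg_proj <- volume_grid(Reduce(`+`, lapply(proj_subj, `[[`, "data")) /
                            length(proj_subj), gt$labels$affine)
  parcels <- generate_parcellation(gt, block_mm = parcel_mm)
  avg_pv <- parcellate(avg_proj, parcels)
  # annotation fixtures correlate with a smoothed log-density of the mean
  # projection map: receptor-density maps are smooth fields, and the raw
  # streamline counts are zero over most of the volume
  shape <- dim(avg_proj$data)
  ann_ref <- volume_grid(array(cpp_smooth3(log1p(avg_proj$data), shape, 2),
                               shape), avg_proj$affine)
  annotations <- lapply(seq_along(annotation_rhos), function(k)
    generate_annotation_map(gt, ann_ref, annotation_rhos[k],
                            seed = seed + 100L + k))
  names(annotations) <- names(annotation_rhos)
  ann_pv <- lapply(annotations, parcellate, parcellation = parcels)
  rhos <- vapply(ann_pv, function(apv)
    vapply(proj_subj, function(pm)
      spearman_spatial(parcellate(pm, parcels), apv), numeric(1)),
    numeric(length(proj_subj)))
  colnames(rhos) <- names(annotation_rhos)
  report <- cohort_inference(rhos)
  ens <- variogram_surrogates(avg_pv, n_surrogates = n_surrogates,
                              seed = seed + 500L)
  surrogate_p <- vapply(ann_pv, function(apv)
    pairwise_surrogate_test(avg_pv, apv, ens)$p, numeric(1))

  log_stage("run-all", sprintf("done in %.1f min",
            as.numeric(difftime(Sys.time(), t0, units = "mins"))),
            verbose = verbose)
  list(ground_truth = gt,
       median_maps = median_maps,
       templates = tmpl,
       stats = stats,
       group_median = group_median,
       conjunction = conj,
       difference = diffm,
       rois = rois,
       recovery = recovery,
       alignment = list(dice_unaligned = dice_unaligned,
                        dice_aligned = dice_aligned),
       connectomes = connectomes,
       hubs = hubs,
       hub_top_subcortical = hub_top,
       lateralization = lat,
       annotation = list(rhos = rhos, report = report,
                         surrogate_p = surrogate_p,
                         flagged = surrogate_p < 0.05,
                         targets = annotation_rhos))
}
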