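# Synthetic cohort generator: determinism, planted structure, BOLD signal law.

test_that("ground truth is deterministic and matches the configured layout", {
  g1 <- generate_ground_truth(cohort_config(), seed = 7)
  g2 <- generate_ground_truth(cohort_config(), seed = 7)
  expect_identical(g1, g2)
  # networks share exactly the subcortical nodes
  shared <- g1$nodes$net_A & g1$nodes$net_B
  expect_true(all(g1$nodes$role[shared] == "subcortical_shared"))
  expect_true(all(g1$nodes$net_A[g1$nodes$role == "subcortical_shared"]))
  expect_true(all(g1$nodes$net_B[g1$nodes$role == "subcortical_shared"]))
  # every rendered label belongs to a defined node
  expect_true(all(unique(as.vector(g1$labels$data)) %in%
                    c(0L, seq_len(nrow(g1$nodes)))))
})

test_that("overlapping node spheres are rejected with both ids named", {
  nodes <- default_nodes()
  nodes$x[nodes$id == "thal_L"] <- nodes$x[nodes$id == "thal_R"]
  nodes$y[nodes$id == "thal_L"] <- nodes$y[nodes$id == "thal_R"]
  nodes$z[nodes$id == "thal_L"] <- nodes$z[nodes$id == "thal_R"]
  err <- expect_error(
    generate_ground_truth(cohort_config(nodes = nodes), seed = 1),
    "overlap")
  expect_match(conditionMessage(err), "thal_L")
  expect_match(conditionMessage(err), "thal_R")
})

test_that("study-scale configuration yields 23 A-seeds and 32 B-seeds", {
  gt <- generate_ground_truth(study_scale_config(), seed = 1)
  cort <- gt$nodes[gt$nodes$role != "subcortical_shared", ]
  expect_equal(sum(cort$net_A), 23L)
  expect_equal(sum(cort$net_B), 32L)
  expect_equal(sum(cort$net_A & cort$hemisphere == "L"), 11L)
  expect_equal(sum(cort$net_A & cort$hemisphere == "R"), 12L)
  expect_equal(sum(cort$net_B & cort$hemisphere == "L"), 19L)
  expect_equal(sum(cort$net_B & cort$hemisphere == "R"), 13L)
})

test_that("invalid configurations are refused", {
  expect_error(generate_ground_truth(cohort_config(shape = c(16, 38, 32))),
               ">= 24")
  cfg <- cohort_config()
  cfg$edges <- rbind(cfg$edges,
                     data.frame(from = "ghost", to = "thal_L", count = 1L))
  expect_error(generate_ground_truth(cfg), "ghost")
  expect_error(generate_ground_truth(cohort_config(noise_sd = 0)), "noise sd")
})

test_that("zero warp amplitude reproduces the template labels exactly", {
  gt <- generate_ground_truth(tiny_config(warp_amplitude_mm = 0), seed = 1)
  sub <- generate_subject(gt, "s1", seed = 5)
  expect_identical(as.vector(sub$seed_labels$data), as.vector(gt$labels$data))
  expect_equal(max(abs(unlist(sub$true_warp$disp))), 0)
})

test_that("subject warps are invertible and streamlines stay in the grid", {
  gt <- generate_ground_truth(tiny_config(), seed = 1)
  for (s in 1:3) {
    sub <- generate_subject(gt, paste0("s", s), seed = 10 + s)
    expect_gt(sub$true_warp$jacobian_min, 0)
    lo <- voxel_to_world(gt$labels$affine, matrix(c(0, 0, 0), 1))
    hi <- voxel_to_world(gt$labels$affine,
                         matrix(dim(gt$labels$data) - 1, 1))
    for (m in sub$streamlines$streamlines) {
      expect_true(all(m >= rep(lo, each = nrow(m)) - 1e-9))
      expect_true(all(m <= rep(hi, each = nrow(m)) + 1e-9))
    }
  }
  # one streamline per unit of edge count
  sub <- generate_subject(gt, "sX", seed = 99)
  expect_length(sub$streamlines$streamlines, sum(gt$edges$count))
})

test_that("with zero signal weight node series are uncorrelated with latents", {
  gt <- generate_ground_truth(tiny_config(signal_weight = 0,
                                          warp_amplitude_mm = 0), seed = 1)
  n_bad <- 0L
  n_seeds <- 40L
  nodeA <- which(gt$nodes$id == "A_L1")
  for (s in seq_len(n_seeds)) {
    sub <- generate_subject(gt, "s", seed = 100 + s)
    vox <- which(sub$seed_labels$data == nodeA)
    series <- colMeans(matrix(sub$bold$data, ncol = dim(sub$bold$data)[4])[vox, ])
    r <- cor(series, sub$latents$A)
    if (abs(r) > 3 / sqrt(length(series))) n_bad <- n_bad + 1L
  }
  # |r| < 3/sqrt(T) should hold in ~99% of seeds; allow a small margin
  expect_lte(n_bad, ceiling(0.05 * n_seeds))
})

test_that("BOLD attenuation follows w / sqrt(w^2 + sigma^2)", {
  gt <- generate_ground_truth(tiny_config(signal_weight = 1, noise_sd = 1,
                                          warp_amplitude_mm = 0), seed = 1)
  nodeA <- which(gt$nodes$id == "A_R2")
  vox <- which(gt$labels$data == nodeA)[1]
  rs <- vapply(seq_len(200L), function(s) {
    sub <- generate_subject(gt, "s", seed = 300 + s)
    series <- matrix(sub$bold$data, ncol = dim(sub$bold$data)[4])[vox, ]
    cor(series, sub$latents$A)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 1 / sqrt(2)), 0.03)
})

test_that("membership volumes are conserved under zero warp", {
  gt <- generate_ground_truth(tiny_config(warp_amplitude_mm = 0), seed = 1)
  sub <- generate_subject(gt, "s1", seed = 1)
  for (nid in seq_len(nrow(gt$nodes))) {
    expect_equal(sum(sub$seed_labels$data == nid),
                 sum(gt$labels$data == nid))
  }
})

test_that("annotation maps hit their target Spearman correlation", {
  gt <- generate_ground_truth(cohort_config(), seed = 1)
  V <- dim(gt$labels$data)
  set.seed(9)
  ref <- volume_grid(array(subcortnet:::cpp_smooth3(rnorm(prod(V)), V, 1), V),
                     gt$labels$affine)
  # exact rank identity
  a1 <- generate_annotation_map(gt, ref, 1, smoothness_mm = 0)
  expect_equal(cor(as.vector(a1$data), as.vector(ref$data),
                   method = "spearman"), 1)
  expect_error(generate_annotation_map(gt, ref, 1, smoothness_mm = 6),
               "incompatible")
  expect_error(generate_annotation_map(gt, ref, 1.2), "rho_target")
  # rho 0: mean empirical correlation near 0 (seeds disjoint from the
  # reference's RNG stream)
  r0 <- vapply(1:100, function(s)
    cor(as.vector(generate_annotation_map(gt, ref, 0, seed = 5000 + s)$data),
        as.vector(ref$data), method = "spearman"), numeric(1))
  expect_true(all(abs(r0) < 0.1))
  expect_lt(abs(mean(r0)), 0.02)
  # rho 0.5 calibration over 200 seeds
  r5 <- vapply(1:200, function(s)
    cor(as.vector(generate_annotation_map(gt, ref, 0.5, seed = 7000 + s)$data),
        as.vector(ref$data), method = "spearman"), numeric(1))
  expect_lt(abs(mean(r5) - 0.5), 0.05)
})

test_that("block parcellation covers the grid with compact labels", {
  gt <- generate_ground_truth(cohort_config(), seed = 1)
  p <- generate_parcellation(gt, block_mm = 8)
  labs <- sort(unique(as.vector(p$data)))
  expect_equal(labs, seq_along(labs))
  expect_true(all(p$data >= 1))
})
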