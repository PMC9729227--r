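# Streamline selection, density maps, connectomes, hub metrics,
# lateralization.

toy_labels <- function() {
  shape <- c(12L, 6L, 6L)
  lab <- array(0L, dim = shape)
  lab[2:3, 3:4, 3:4] <- 3L
  lab[9:10, 3:4, 3:4] <- 7L
  volume_grid(lab, diag(4))
}

test_that("streamlines are retained iff they cross >= 2 distinct ROIs", {
  lab <- toy_labels()
  through <- matrix(c(1, 3, 3, 10, 3, 3), ncol = 3, byrow = TRUE)   # hits 3 & 7
  outside <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 3, byrow = TRUE)    # misses all
  one_only <- matrix(c(2, 2, 2, 2.5, 3.5, 3.5), ncol = 3, byrow = TRUE)
  ss <- streamline_set(list(through, outside, one_only), lab)
  sel <- select_streamlines(ss, lab)
  expect_equal(sel$index, 1L)
  expect_equal(sel$hits[[1]], c(3L, 7L))
  # exhaustive rasterization oracle for the retained segment
  tpts <- seq(0, 1, by = 0.01)
  pts <- cbind(1 + 9 * tpts, 3, 3)
  vox <- unique(round(pts))
  hit_labels <- unique(lab$data[vox + 1])  # integer grid, identity affine
  expect_setequal(sel$hits[[1]], sort(hit_labels[hit_labels > 0]))
})

test_that("density maps count each streamline once per voxel", {
  lab <- toy_labels()
  a <- matrix(c(1, 3, 3, 6, 3, 3), ncol = 3, byrow = TRUE)
  b <- matrix(c(6, 3, 3, 10, 3, 3), ncol = 3, byrow = TRUE)
  ss <- streamline_set(list(a, b), lab)
  dm <- density_map(ss)
  expect_equal(dm$data[7, 4, 4], 2L)       # shared voxel (6,3,3) 0-based
  expect_equal(max(dm$data), 2L)
  expect_equal(binarize_map(dm)$data[7, 4, 4], 1L)
  # total mass equals the sum of distinct voxels per streamline
  va <- subcortnet:::streamline_voxels(a, dim(lab$data), lab$affine)
  vb <- subcortnet:::streamline_voxels(b, dim(lab$data), lab$affine)
  expect_equal(sum(dm$data), length(va) + length(vb))
  # empty set gives a zero map
  expect_equal(max(density_map(streamline_set(list(), lab))$data), 0L)
})

test_that("group overlap is the mean of binarized maps", {
  aff <- diag(4)
  mk <- function(v) volume_grid(array(v, dim = c(1, 1, 2)), aff)
  ov <- group_overlap(list(mk(c(1, 0)), mk(c(1, 1)), mk(c(0, 0)),
                           mk(c(1, 0))))
  expect_equal(as.numeric(ov$data), c(0.75, 0.25))
})

test_that("connectome counts all unordered ROI pairs per streamline", {
  nodes <- data.frame(id = 1:4, name = paste0("n", 1:4),
                      hemisphere = c("L", "R", "L", "R"), role = "cortical_A")
  cn <- connectome_from_hits(list(c(1L, 2L)), nodes)
  expect_equal(cn$structural_count["n1", "n2"], 1L)
  expect_equal(sum(cn$structural_count), 2L)
  cn3 <- connectome_from_hits(list(c(1L, 2L, 3L)), nodes)
  expect_equal(sum(cn3$structural_count) / 2, 3)  # C(3,2) pairs
  # binarization carries no threshold
  cn17 <- connectome_from_hits(rep(list(c(1L, 2L)), 17), nodes)
  expect_equal(cn17$structural_count["n1", "n2"], 17L)
  expect_equal(cn17$binary["n1", "n2"], 1L)
  expect_equal(cn17$binary["n3", "n4"], 0L)
  expect_error(connectome_from_hits(list(c(1L, 9L)), nodes), "9")
  # symmetry and zero diagonal
  expect_equal(cn3$structural_count, t(cn3$structural_count))
  expect_equal(unname(diag(cn3$structural_count)), rep(0L, 4))
})

mk_connectome <- function(adj, hemi = NULL) {
  N <- nrow(adj)
  nodes <- data.frame(id = seq_len(N), name = paste0("n", seq_len(N)),
                      hemisphere = hemi %||% rep(c("L", "R"), length.out = N),
                      role = "cortical_A")
  dimnames(adj) <- list(nodes$name, nodes$name)
  structure(list(nodes = nodes, structural_count = adj, binary = (adj > 0) * 1L,
                 subject_id = "s"), class = "connectome")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hub metrics reproduce closed forms on canonical graphs", {
  # complete graph K5: degree 1, betweenness 0
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  hm <- hub_metrics(list(mk_connectome(K5)))
  expect_equal(unname(hm$table$median_degree), rep(1, 5))
  expect_equal(unname(hm$table$median_betweenness), rep(0, 5))
  # star graph S5: centre degree 1 and betweenness 1, leaves 0.25 / 0
  S5 <- matrix(0L, 5, 5); S5[1, 2:5] <- 1L; S5[2:5, 1] <- 1L
  hm <- hub_metrics(list(mk_connectome(S5)))
  expect_equal(hm$table$median_degree[1], 1)
  expect_equal(hm$table$median_betweenness[1], 1)
  expect_equal(unname(hm$table$median_degree[2:5]), rep(0.25, 4))
  expect_equal(unname(hm$table$median_betweenness[2:5]), rep(0, 4))
  # path graph A-B-C-D: middle nodes betweenness 2/3
  P4 <- matrix(0L, 4, 4)
  P4[cbind(1:3, 2:4)] <- 1L; P4[cbind(2:4, 1:3)] <- 1L
  hm <- hub_metrics(list(mk_connectome(P4)))
  expect_equal(unname(hm$table$median_betweenness), c(0, 2/3, 2/3, 0))
})

test_that("hub metrics equal the all-pairs BFS oracle on random graphs", {
  set.seed(30)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    adj <- matrix(0L, N, N)
    upper <- which(upper.tri(adj))
    on <- sample(upper, max(N - 1, rbinom(1, length(upper), 0.35)))
    adj[on] <- 1L
    adj <- adj + t(adj)
    hm <- hub_metrics(list(mk_connectome(adj)))
    expect_equal(unname(hm$table$median_degree), oracle_degree(adj))
    expect_equal(unname(hm$table$median_betweenness), oracle_betweenness(adj),
                 tolerance = 1e-12)
  }
})

test_that("median aggregation across subjects is per node", {
  S5 <- matrix(0L, 5, 5); S5[1, 2:5] <- 1L; S5[2:5, 1] <- 1L
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  hm <- hub_metrics(list(mk_connectome(S5), mk_connectome(S5),
                         mk_connectome(K5)))
  expect_equal(hm$table$median_degree[1], 1)
  expect_equal(hm$table$median_degree[2], 0.25)  # median of (.25,.25,1)
  expect_error(hub_metrics(list(mk_connectome(matrix(0L, 2, 2)))), "3 nodes")
})

test_that("lateralization test gates on normality and detects asymmetry", {
  set.seed(31)
  # planted asymmetry: right 20% larger
  left <- rnorm(20, 10, 0.5)
  right <- left * 1.2 + rnorm(20, 0, 0.2)
  res <- lateralization_test(left, right)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, "right > left")
  # degenerate: zero-variance differences
  res0 <- lateralization_test(rep(1, 8), rep(1, 8))
  expect_true(res0$degenerate)
  expect_error(lateralization_test(1:3, 2:4), ">= 6")
})

test_that("Wilcoxon branch matches exhaustive signed-rank enumeration", {
  # an extreme outlier difference forces the non-normal branch; |d| has no
  # ties, so the exact signed-rank distribution applies
  left <- rep(0, 12)
  d <- c(0.3, -0.11, 0.25, 0.16, -0.06, 0.2, 0.35, -0.14, 0.12, 0.05, 0.4, 6)
  right <- left + d
  expect_lt(shapiro.test(d)$p.value, 0.05)
  res <- lateralization_test(left, right)
  expect_equal(res$test, "Wilcoxon signed-rank")
  # exhaustive oracle over all 2^12 sign patterns of the ranked |d|
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
  v_null <- as.numeric(signs %*% rk)
  p_two_exact <- min(1, 2 * min(mean(v_null >= v_obs), mean(v_null <= v_obs)))
  expect_equal(res$p, p_two_exact, tolerance = 1e-12)
})

test_that("hemispheric tract volume counts same-hemisphere connections only", {
  lab <- toy_labels()  # ROI 3 (left half) and ROI 7 (right half)
  tab <- data.frame(id = c(3L, 7L), hemisphere = c("L", "L"))
  cross <- matrix(c(1, 3, 3, 10, 3, 3), ncol = 3, byrow = TRUE)
  ss <- streamline_set(list(cross), lab)
  # both ROIs declared left: the crossing streamline counts for L, not R
  vol_L <- hemispheric_tract_volume(ss, lab, tab, "L")
  vol_R <- hemispheric_tract_volume(ss, lab, tab, "R")
  dm <- density_map(streamline_set(list(cross), lab))
  expect_equal(vol_L, sum(dm$data > 0) * 1 / 1000)
  expect_equal(vol_R, 0)
})

test_that("symmetric cohorts do not produce spurious lateralization", {
  set.seed(32)
  n_rej <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    base <- rnorm(12, 20, 2)
    left <- base + rnorm(12, 0, 1)
    right <- base + rnorm(12, 0, 1)
    res <- lateralization_test(left, right)
    if (!res$degenerate && res$p < 0.05) n_rej <- n_rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(n_rej / n_rep, 0.05 + 2 * se)
})
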