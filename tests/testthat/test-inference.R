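# TFCE, permutation inference, conjunction/difference, ROI extraction.

test_that("TFCE handles degenerate and monotone cases", {
  aff <- diag(4)
  zero <- volume_grid(array(0, dim = c(6, 6, 6)), aff)
  expect_equal(tfce_enhance(zero)$data, zero$data)
  set.seed(20)
  a <- array(rnorm(6^3), dim = c(6, 6, 6))
  t1 <- tfce_enhance(volume_grid(a, aff))$data
  t2 <- tfce_enhance(volume_grid(2.5 * a, aff))$data
  # scaling up the input cannot shrink the enhancement magnitude anywhere,
  # and signs are preserved
  expect_true(all(abs(t2) - abs(t1) > -1e-12))
  expect_true(all(sign(t2) == sign(t1) | t1 == 0))
  expect_error(tfce_enhance(volume_grid(a, aff), H = 0), "H and E")
  expect_error(tfce_enhance(volume_grid(a, aff), n_steps = 5), "n_steps")
})

test_that("an isolated unit voxel integrates to the discrete Riemann sum", {
  a <- array(0, dim = c(9, 9, 9))
  a[5, 5, 5] <- 1
  v <- tfce_enhance(volume_grid(a, diag(4)), H = 2, E = 0.5,
                    n_steps = 100)$data[5, 5, 5]
  # independent closed-form oracle: sum over h = k/100 of 1^0.5 * h^2 * 0.01
  expected <- sum((seq_len(100) / 100)^2) * 0.01
  expect_equal(v, expected, tolerance = 1e-12)
  expect_equal(expected, 0.33835)
})

test_that("TFCE equals the brute-force threshold-sum oracle on random maps", {
  set.seed(21)
  for (i in 1:8) {
    a <- array(rnorm(8^3), dim = c(8, 8, 8))
    mine <- tfce_enhance(volume_grid(a, diag(4)), n_steps = 25)$data
    ref <- oracle_tfce(a, n_steps = 25)
    expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-9)
  }
})

test_that("sampled sign-flip p-values match exhaustive enumeration", {
  set.seed(22)
  n <- 10
  shape <- c(8L, 8L, 6L)
  V <- prod(shape)
  maps <- lapply(1:n, function(i) {
    a <- array(rnorm(V, sd = 1), dim = shape)
    a[3:5, 3:5, 2:4] <- a[3:5, 3:5, 2:4] + 0.8
    volume_grid(a, diag(4))
  })
  n_perm <- 1000L
  res <- one_sample_permutation(maps, n_permutations = n_perm, seed = 5,
                                n_steps = 40)
  # exhaustive oracle over all 2^10 sign patterns
  X <- t(vapply(maps, function(m) as.numeric(m$data), numeric(V)))
  ss <- colSums(X^2)
  tfce_of <- function(signs) {
    mu <- as.numeric(signs %*% X) / n
    v <- (ss - n * mu^2) / (n - 1)
    tt <- ifelse(v > 0, mu / sqrt(v / n), 0)
    max(subcortnet:::cpp_tfce(tt, shape, 2, 0.5, 40L))
  }
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(grid, 1, tfce_of)
  obs <- res$tfce_map$data
  p_exact <- (1 + vapply(as.numeric(obs), function(o)
    sum(null_max >= o), numeric(1))) / (1 + length(null_max))
  p_samp <- as.numeric(res$fwe_p_map$data)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_true(all(abs(p_samp - p_exact) <= 3 * se + 1 / n_perm))
})

test_that("permutation inference refuses tiny cohorts and degenerate maps", {
  maps <- lapply(1:5, function(i)
    volume_grid(array(rnorm(64), dim = c(4, 4, 4)), diag(4)))
  expect_error(one_sample_permutation(maps, 100), "fewer than 8")
  maps8 <- lapply(1:8, function(i)
    volume_grid(array(rnorm(64), dim = c(4, 4, 4)), diag(4)))
  expect_error(one_sample_permutation(maps8, 50), ">= 100")
  # a voxel constant across subjects gets t = 0
  maps0 <- lapply(1:8, function(i) {
    a <- array(rnorm(64), dim = c(4, 4, 4)); a[1, 1, 1] <- 0.42; volume_grid(a, diag(4))
  })
  res <- one_sample_permutation(maps0, 100, seed = 1, n_steps = 20)
  expect_equal(res$t_map$data[1, 1, 1], 0)
})

test_that("conjunction is the voxelwise minimum of z maps", {
  set.seed(23)
  shape <- c(5L, 5L, 5L)
  mk <- function(shift) lapply(1:8, function(i)
    volume_grid(array(rnorm(prod(shape)) + shift, dim = shape), diag(4)))
  sA <- one_sample_permutation(mk(0.5), 100, seed = 1, n_steps = 20)
  sB <- one_sample_permutation(mk(0.2), 100, seed = 2, n_steps = 20)
  cj <- conjunction_map(sA, sB)
  zA <- subcortnet:::z_transform_t(sA$t_map$data, 7)
  zB <- subcortnet:::z_transform_t(sB$t_map$data, 7)
  expect_equal(cj$z_min$data, array(pmin(zA, zB), dim = shape))
  # identical inputs: conjunction equals the common z map
  cj2 <- conjunction_map(sA, sA)
  expect_equal(cj2$z_min$data, zA)
  # zero t in one map forces the conjunction <= 0 there
  sA0 <- sA
  sA0$t_map$data[2, 2, 2] <- 0
  cj3 <- conjunction_map(sA0, sB)
  expect_lte(cj3$z_min$data[2, 2, 2], 0)
})

test_that("difference maps are antisymmetric and exact", {
  aff <- diag(4)
  a <- volume_grid(array(0.35, dim = c(3, 3, 3)), aff)
  b <- volume_grid(array(0.15, dim = c(3, 3, 3)), aff)
  expect_equal(difference_map(a, b)$data[1], 0.2)
  expect_equal(difference_map(a, a)$data, array(0, dim = c(3, 3, 3)))
  expect_equal(difference_map(a, b)$data, -difference_map(b, a)$data)
})

test_that("ROI extraction labels components and centroids like the oracle", {
  shape <- c(12L, 12L, 6L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-30, -11, -5)
  p <- array(1, dim = shape)
  r <- array(0, dim = shape)
  # two disjoint clusters of 5 and 7 voxels, plus a 1-voxel speck
  c1 <- rbind(c(2,2,2), c(3,2,2), c(2,3,2), c(2,2,3), c(3,3,3))
  c2 <- rbind(c(9,9,2), c(10,9,2), c(9,10,2), c(10,10,2), c(9,9,3),
              c(10,9,3), c(9,10,3))
  speck <- rbind(c(6, 12, 6))
  for (v in seq_len(nrow(c1))) { p[c1[v,1],c1[v,2],c1[v,3]] <- 0.001; r[c1[v,1],c1[v,2],c1[v,3]] <- 0.5 }
  for (v in seq_len(nrow(c2))) { p[c2[v,1],c2[v,2],c2[v,3]] <- 0.001; r[c2[v,1],c2[v,2],c2[v,3]] <- 0.3 }
  p[speck[1],speck[2],speck[3]] <- 0.001; r[speck[1],speck[2],speck[3]] <- 0.9
  stat <- structure(list(
    fwe_p_map = volume_grid(p, aff),
    t_map = volume_grid(array(1, shape), aff), n_subjects = 10), class = "stat_map")
  rois <- extract_rois(stat, volume_grid(r, aff),
                       volume_grid(array(1, shape), aff), min_voxels = 3L)
  expect_equal(nrow(rois$table), 2L)
  expect_setequal(rois$table$n_voxels, c(5L, 7L))
  # centroid oracle: unweighted mean of member world coordinates
  w1 <- voxel_to_world(aff, c1 - 1)
  i1 <- which(rois$table$n_voxels == 5L)
  expect_equal(unlist(rois$table[i1, c("x", "y", "z")]),
               c(x = mean(w1[, 1]), y = mean(w1[, 2]), z = mean(w1[, 3])))
  # hemisphere from centre-of-gravity x sign
  expect_equal(rois$table$hemisphere[i1],
               if (mean(w1[, 1]) < -1) "L" else "R")
  # labelling agrees with the BFS component oracle
  sel <- (p < 0.05) & (r > 0.1)
  olab <- oracle_components(sel)
  keep <- which(tabulate(olab[olab > 0]) >= 3L)
  expect_equal(sum(rois$labels$data > 0), sum(olab %in% keep))
})

test_that("an empty ROI result is a valid empty set", {
  shape <- c(6L, 6L, 6L)
  stat <- structure(list(
    fwe_p_map = volume_grid(array(1, shape), diag(4)),
    t_map = volume_grid(array(0, shape), diag(4)), n_subjects = 10),
    class = "stat_map")
  rois <- extract_rois(stat, volume_grid(array(0, shape), diag(4)),
                       volume_grid(array(1, shape), diag(4)))
  expect_equal(nrow(rois$table), 0L)
  expect_true(all(rois$labels$data == 0L))
})
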