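# Independent oracles used across the suite. These deliberately avoid the
# package's compiled kernels: components are grown by BFS in plain R, TFCE is
# a literal threshold-sum loop, and centralities follow Brandes' accounting
# with explicit shortest-path counting.

# 26-connected component labels of a logical 3D array, scan order.
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    front <- v
    lab[v] <- cur
    while (length(front)) {
      nf <- integer(0)
      for (u in front) {
        ui <- arrayInd(u, d)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (!dx && !dy && !dz) next
          w <- ui + c(dx, dy, dz)
          if (any(w < 1) || any(w > d)) next
          li <- w[1] + d[1] * ((w[2] - 1) + d[2] * (w[3] - 1))
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- cur
            nf <- c(nf, li)
          }
        }
      }
      front <- nf
    }
  }
  lab
}

# Brute-force threshold-sum TFCE (both signs, 26-connectivity).
oracle_tfce <- function(a, H = 2, E = 0.5, n_steps = 100) {
  d <- dim(a)
  out <- array(0, d)
  for (sgn in c(1, -1)) {
    s <- sgn * a
    mx <- max(s)
    if (mx <= 0) next
    dh <- mx / n_steps
    for (k in seq_len(n_steps)) {
      h <- k * dh
      mask <- s >= h
      lab <- oracle_components(mask)
      sz <- tabulate(lab[lab > 0])
      sel <- which(mask)
      out[sel] <- out[sel] + sgn * sz[lab[sel]]^E * h^H * dh
    }
  }
  out
}

# Degree centrality, fraction of other nodes adjacent.
oracle_degree <- function(adj) {
  rowSums(adj > 0) / (nrow(adj) - 1)
}

# Betweenness centrality by Brandes' algorithm with explicit BFS,
# normalized by 2 / ((N-1)(N-2)).
oracle_betweenness <- function(adj) {
  N <- nrow(adj)
  bc <- numeric(N)
  for (s in seq_len(N)) {
    dist <- rep(-1L, N)
    sigma <- numeric(N)
    sigma[s] <- 1
    dist[s] <- 0L
    preds <- vector("list", N)
    ord <- integer(0)
    Q <- s
    while (length(Q)) {
      v <- Q[1]
      Q <- Q[-1]
      ord <- c(ord, v)
      for (w in which(adj[v, ] > 0)) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          Q <- c(Q, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(N)
    for (w in rev(ord)) {
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  (bc / 2) / ((N - 1) * (N - 2) / 2)
}

# Gaussian blob map fixture on an isotropic unit grid.
make_blob_map <- function(shape, centre, width = 3, affine = diag(4)) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  a <- array(exp(-((idx[, 1] - centre[1])^2 + (idx[, 2] - centre[2])^2 +
                   (idx[, 3] - centre[3])^2) / (2 * width^2)), dim = shape)
  volume_grid(a, affine)
}

# Tiny cohort configuration used by tests that do not need the full default
# scale (fewer timepoints; same spatial layout).
tiny_config <- function(...) {
  cohort_config(n_subjects = 6L, n_timepoints = 60L, ...)
}
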