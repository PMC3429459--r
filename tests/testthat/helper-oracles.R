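# Independent oracles and shared fixtures for the test suite.

# Literal transcription of the two-step floating catchment computation:
# R_j = S_j / sum_k W(t_kj) P_k  (over t_kj <= t0, skipping empty catchments)
# A_k = scale * sum_j W(t_kj) R_j (over t_kj <= t0)
# Written as explicit loops, independent of the vectorized implementation.
oracle_2sfca <- function(tt, s, p, wfun, t0 = 30, scale = 1e4) {
  nb <- nrow(tt); nf <- ncol(tt)
  r <- numeric(nf)
  for (j in seq_len(nf)) {
    denom <- 0
    for (k in seq_len(nb)) {
      if (is.finite(tt[k, j]) && tt[k, j] <= t0) {
        denom <- denom + wfun(tt[k, j]) * p[k]
      }
    }
    r[j] <- if (denom > 0) s[j] / denom else 0
  }
  a <- numeric(nb)
  for (k in seq_len(nb)) {
    for (j in seq_len(nf)) {
      if (is.finite(tt[k, j]) && tt[k, j] <= t0) {
        a[k] <- a[k] + wfun(tt[k, j]) * r[j]
      }
    }
  }
  scale * a
}

# All-pairs Bellman-Ford over an undirected edge list; brute-force oracle for
# shortest-path travel times on small networks.
oracle_bellman_ford <- function(n_nodes, edges) {
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (src in seq_len(n_nodes)) {
    dist <- rep(Inf, n_nodes)
    dist[src] <- 0
    for (iter in seq_len(n_nodes - 1)) {
      for (e in seq_len(nrow(edges))) {
        a <- edges$from[e]; b <- edges$to[e]; w <- edges$minutes[e]
        if (dist[a] + w < dist[b]) dist[b] <- dist[a] + w
        if (dist[b] + w < dist[a]) dist[a] <- dist[b] + w
      }
    }
    d[src, ] <- dist
  }
  d
}

# The worked 3-block-group / 2-facility example: travel times in minutes,
# one machine per facility, 100 women 40+ per block group.
toy_times <- function() {
  matrix(c(5, 25,
           15, 15,
           35, 5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("b1", "b2", "b3"), c("f1", "f2")))
}

# Random accessibility instance: times ~ U(0, 45) (some beyond the 30-min
# catchment), integer machines >= 1, positive populations.
random_instance <- function(n_bg, n_fac, seed) {
  withr::with_seed(seed, {
    tt <- matrix(stats::runif(n_bg * n_fac, 0, 45), n_bg, n_fac,
                 dimnames = list(paste0("b", seq_len(n_bg)),
                                 paste0("f", seq_len(n_fac))))
    list(tt = tt,
         s = stats::setNames(1 + stats::rpois(n_fac, 2), colnames(tt)),
         p = stats::setNames(stats::runif(n_bg, 50, 2000), rownames(tt)))
  })
}

# A rook-contiguity adjacency matrix for an r x c lattice.
lattice_adjacency <- function(r, c) {
  n <- r * c
  adj <- matrix(0, n, n)
  id <- function(i, j) (i - 1) * c + j
  for (i in seq_len(r)) for (j in seq_len(c)) {
    if (i < r) adj[id(i, j), id(i + 1, j)] <- adj[id(i + 1, j), id(i, j)] <- 1
    if (j < c) adj[id(i, j), id(i, j + 1)] <- adj[id(i, j + 1), id(i, j)] <- 1
  }
  adj
}

# Small region used by several tests.
small_region <- function(seed = 7, n_bg = 60, n_fac = 8) {
  generate_region(region_spec(n_blockgroups = n_bg, n_facilities = n_fac,
                              seed = seed))
}
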