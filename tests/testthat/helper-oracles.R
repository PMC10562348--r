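# Independent oracles used across the suite.  These deliberately use naive
# algorithms (double loops, dense linear algebra) and share no code with the
# package internals they check.

# O(n^2) pairwise potential sum over a charge matrix
brute_force_potential <- function(q) {
  L <- nrow(q)
  v <- matrix(0, L, L)
  for (r1 in 1:L) for (c1 in 1:L) {
    acc <- 0
    for (r2 in 1:L) for (c2 in 1:L) {
      if (r1 == r2 && c1 == c2) next
      if (q[r2, c2] == 0) next
      acc <- acc + q[r2, c2] / sqrt((r1 - r2)^2 + (c1 - c2)^2)
    }
    v[r1, c1] <- acc
  }
  v
}

# dense nodal solve of an arbitrary two-contact resistor network
dense_current_oracle <- function(n_nodes, edges, source_nodes, sink_nodes, V = 1) {
  G <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; g <- 1 / edges$R[k]
    G[i, j] <- G[i, j] + g
    G[j, i] <- G[j, i] + g
  }
  Lap <- diag(rowSums(G)) - G
  fixed <- c(source_nodes, sink_nodes)
  vfix <- c(rep(V, length(source_nodes)), rep(0, length(sink_nodes)))
  free <- setdiff(seq_len(n_nodes), fixed)
  v <- numeric(n_nodes)
  v[fixed] <- vfix
  if (length(free))
    v[free] <- solve(Lap[free, free, drop = FALSE],
                     -Lap[free, fixed, drop = FALSE] %*% vfix)
  # current out of the source contact
  I <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; g <- 1 / edges$R[k]
    si <- i %in% source_nodes; sj <- j %in% source_nodes
    if (si && !sj) I <- I + g * (v[i] - v[j])
    if (sj && !si) I <- I + g * (v[j] - v[i])
  }
  I
}

# random lattice resistor network as the package structures it
random_small_net <- function(L = 5L, seed = 1L) {
  set.seed(seed)
  geom_edges <- list()
  idx <- function(r, c) (c - 1L) * L + r
  ii <- integer(0); jj <- integer(0)
  for (r in 1:L) for (c in 1:L) {
    if (r < L) { ii <- c(ii, idx(r, c)); jj <- c(jj, idx(r + 1L, c)) }
    if (c < L) { ii <- c(ii, idx(r, c)); jj <- c(jj, idx(r, c + 1L)) }
  }
  R <- 10^stats::runif(length(ii), 0, 3)
  structure(list(n_nodes = L * L,
                 edges = data.frame(i = ii, j = jj, d = 1),
                 R = matrix(R, ncol = 1L),
                 gamma = NA_real_,
                 source_nodes = idx(1L, 1:L),
                 sink_nodes = idx(L, 1:L),
                 applied_potential = 1),
            class = "resistor_network")
}

tiny_config <- function(...) {
  qs_config(grid_side = 12L, initial_fill = 0.1, q_max = 12L, n_steps = 20L,
            seed = 5L, ...)
}
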