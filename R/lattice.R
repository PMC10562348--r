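# Lattice geometry: neighbor tables, the inverse-distance kernel of the
# long-range potential, and the undirected neighbor-pair (edge) list of the
# resistor network.  Everything here depends only on (grid_side, neighborhood)
# and is cached in a package-local environment.

.luxnet_cache <- new.env(parent = emptyenv())

site_coords <- function(L) {
  # column-major site index -> (row, col), matching R matrix indexing
  idx <- seq_len(L * L)
  cbind(row = ((idx - 1L) %% L) + 1L, col = ((idx - 1L) %/% L) + 1L)
}

neighbor_offsets <- function(neighborhood) {
  if (neighborhood == 4L) {
    off <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    off <- cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                 dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  off
}

#' @keywords internal
lattice_geometry <- function(L, neighborhood) {
  key <- sprintf("geom_%d_%d", L, neighborhood)
  if (!is.null(.luxnet_cache[[key]])) return(.luxnet_cache[[key]])
  n <- L * L
  xy <- site_coords(L)
  off <- neighbor_offsets(neighborhood)
  k <- nrow(off)
  nbr <- matrix(NA_integer_, n, k)
  dist <- numeric(k)
  for (j in seq_len(k)) {
    r <- xy[, "row"] + off[j, "dr"]
    c <- xy[, "col"] + off[j, "dc"]
    ok <- r >= 1L & r <= L & c >= 1L & c <= L   # hard walls, no wrap-around
    nbr[ok, j] <- (c[ok] - 1L) * L + r[ok]
    dist[j] <- sqrt(sum(off[j, ]^2))
  }
  # undirected edge list i < j with Euclidean length
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nbr)
  dd <- rep(dist, each = n)
  keep <- !is.na(jj) & ii < jj
  edges <- list(i = ii[keep], j = jj[keep], d = dd[keep])
  edges$key <- edges$i + n * edges$j          # unique key per unordered pair
  geom <- list(L = L, n = n, k = k, xy = xy, nbr = nbr, nbr_dist = dist,
               edges = edges)
  .luxnet_cache[[key]] <- geom
  geom
}

#' @keywords internal
inverse_distance_kernel <- function(L) {
  key <- sprintf("kern_%d", L)
  if (!is.null(.luxnet_cache[[key]])) return(.luxnet_cache[[key]])
  xy <- site_coords(L)
  dx <- outer(xy[, "row"], xy[, "row"], "-")
  dy <- outer(xy[, "col"], xy[, "col"], "-")
  K <- 1 / sqrt(dx * dx + dy * dy)
  diag(K) <- 0                                 # self-term excluded
  .luxnet_cache[[key]] <- K
  K
}
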