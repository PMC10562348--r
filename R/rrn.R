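#' Hill response of a channel
#'
#' The channel between neighboring sites n and m responds to the two-step
#' average of the charges at its endpoints,
#' `W = (Q_n(t) + Q_m(t))/4 + (Q_n(t-1) + Q_m(t-1))/4`,
#' through the Hill function `h = W^gamma / (g^gamma + W^gamma)`.  `g` is the
#' charge level giving half response; the Hill number `gamma` sets how sharply
#' the response saturates.  `h = 0` when `W = 0`.
#'
#' @param W non-negative channel drive (charge units); vectorised.
#' @param g half-response constant (> 0).
#' @param gamma Hill number (> 0).
#' @return response in `[0, 1]`.
#' @export
hill_response <- function(W, g, gamma) {
  stopifnot(g > 0, gamma > 0)
  h <- ifelse(W > 0, 1 / (1 + (g / W)^gamma), 0)
  as.numeric(h)
}

#' Channel drive from a colony state
#'
#' @param state a `colony_state` carrying `q` and `q_prev`.
#' @param i,j site indices of the channel endpoints (vectorised).
#' @return the two-step average drive `W` of each channel.
#' @export
channel_drive <- function(state, i, j) {
  (state$q[i] + state$q[j]) / 4 + (state$q_prev[i] + state$q_prev[j]) / 4
}

#' Channel resistance
#'
#' Linear interpolation between the fully-open (`h = 1`, resistivity
#' `rho_min`) and fully-closed (`h = 0`, resistivity `rho_max`) channel,
#' scaled by the channel length `D`:
#' `R = D * (rho_min * h + rho_max * (1 - h))`.
#'
#' @param D channel length (lattice units, > 0).
#' @param h Hill response in `[0, 1]`.
#' @param rho_min,rho_max resistivity bounds.
#' @return resistance (arbitrary units).
#' @export
channel_resistance <- function(D, h, rho_min, rho_max) {
  if (any(h < 0 | h > 1)) stop("Hill response h outside [0, 1]", call. = FALSE)
  stopifnot(all(D > 0))
  D * (rho_min * h + rho_max * (1 - h))
}

#' Assemble the random resistor network of a colony state
#'
#' Every neighbor pair of the lattice is an edge.  Pairs joined by an open
#' channel get the Hill-modulated resistance of [channel_resistance()]; all
#' other pairs carry the background resistance `D * rho_max`, so the network
#' is always connected and the unopened paths are negligible at the default
#' 1:1000 resistivity contrast.  Ideal contacts (equipotential bus bars) span
#' the first and last lattice rows; a unit potential difference is applied.
#'
#' @param state a `colony_state` (charges at t and t-1 set the Hill drive).
#' @param links a `link_set` from the current step.
#' @param config a [qs_config()].
#' @param gamma Hill number(s); defaults to `config$hill_gamma`.  With several
#'   values the network carries one resistance vector per value.
#' @return a `resistor_network`: list with `n_nodes`, `edges` (data.frame
#'   `i, j, d`), resistance matrix `R` (edges x gamma), `source_nodes`,
#'   `sink_nodes`, `applied_potential`.
#' @export
assemble_network <- function(state, links, config, gamma = config$hill_gamma) {
  L <- nrow(state$q)
  geom <- lattice_geometry(L, config$neighborhood)
  if (length(links$donor) && links$n_sites != geom$n)
    stop("link set was built on a different lattice (", links$n_sites,
         " sites vs ", geom$n, ")", call. = FALSE)
  ed <- geom$edges
  n_edge <- length(ed$i)
  R <- matrix(rep(ed$d * config$rho_max, length(gamma)), n_edge, length(gamma))
  if (length(links$donor)) {
    key <- pmin(links$donor, links$receiver) +
      geom$n * pmax(links$donor, links$receiver)
    eid <- unique(match(key, ed$key))
    W <- channel_drive(state, ed$i[eid], ed$j[eid])
    for (gi in seq_along(gamma)) {
      h <- hill_response(W, config$hill_g, gamma[gi])
      R[eid, gi] <- channel_resistance(ed$d[eid], h, config$rho_min, config$rho_max)
    }
  }
  net <- list(n_nodes = geom$n,
              edges = data.frame(i = ed$i, j = ed$j, d = ed$d),
              R = R,
              gamma = gamma,
              source_nodes = which(geom$xy[, "row"] == 1L),
              sink_nodes = which(geom$xy[, "row"] == L),
              applied_potential = 1)
  class(net) <- "resistor_network"
  net
}

#' Solve the Kirchhoff node equations of a resistor network
#'
#' The source and sink contacts are ideal (equipotential); with the applied
#' potential V across them, node potentials are obtained from the sparse
#' conductance Laplacian by a Cholesky factorisation, and the total current
#' entering at the source contact is returned.  The node-law residual is
#' checked against `tol` (relative, default 1e-8).
#'
#' @param net a `resistor_network` (or the same structure built by hand, e.g.
#'   by [make_fixture()]).
#' @param column which resistance column (gamma value) to solve; default 1.
#' @param tol relative residual bound for current conservation.
#' @param cache_key optional string; when the sparsity pattern of the network
#'   is known to be identical across calls (repeated lattice readouts), the
#'   symbolic Cholesky analysis is cached under this key and only the numeric
#'   factorisation is redone.
#' @return total current (arbitrary units).
#' @export
solve_current <- function(net, column = 1L, tol = 1e-8, cache_key = NULL) {
  g <- 1 / net$R[, column]
  solve_current_g(net, g, tol, cache_key)
}

# shared worker: conductances g on net$edges
solve_current_g <- function(net, g, tol = 1e-8, cache_key = NULL) {
  n <- net$n_nodes
  src <- net$source_nodes
  snk <- net$sink_nodes
  if (length(intersect(src, snk)))
    stop("source and sink contacts overlap", call. = FALSE)
  V <- net$applied_potential
  role <- integer(n)                    # 0 interior, 1 source, 2 sink
  role[src] <- 1L
  role[snk] <- 2L
  interior <- which(role == 0L)
  idx <- integer(n)
  idx[interior] <- seq_along(interior)
  ei <- net$edges$i; ej <- net$edges$j
  ri <- role[ei]; rj <- role[ej]

  m <- length(interior)
  v_full <- numeric(n)
  v_full[src] <- V
  if (m) {
    ii <- ri == 0L & rj == 0L           # interior-interior
    ic <- xor(ri == 0L, rj == 0L)       # interior-contact
    a_i <- idx[ei[ii]]; a_j <- idx[ej[ii]]
    tab <- function(nodes, w) {
      out <- numeric(m)
      if (length(nodes)) {
        s <- rowsum(w, idx[nodes])
        out[as.integer(rownames(s))] <- s[, 1]
      }
      out
    }
    # diagonal: total conductance at each interior node
    int_end <- c(ei[ii], ej[ii], ifelse(ri[ic] == 0L, ei[ic], ej[ic]))
    dii <- tab(int_end, c(g[ii], g[ii], g[ic]))
    if (any(dii == 0))
      stop("resistor network disconnected: interior node(s) ",
           paste(interior[which(dii == 0)][1:min(3, sum(dii == 0))], collapse = ", "),
           " have no incident edges", call. = FALSE)
    A <- Matrix::sparseMatrix(i = c(seq_len(m), a_i, a_j),
                              j = c(seq_len(m), a_j, a_i),
                              x = c(dii, -g[ii], -g[ii]),
                              dims = c(m, m))
    # rhs: conductance into the source contact, held at potential V
    to_src <- ic & (ri == 1L | rj == 1L)
    b <- tab(ifelse(role[ei] == 0L, ei, ej)[to_src], g[to_src]) * V
    v_int <- tryCatch({
      if (!is.null(cache_key)) {
        As <- Matrix::forceSymmetric(A)
        ch <- .luxnet_cache[[cache_key]]
        ch <- if (is.null(ch)) Matrix::Cholesky(As, LDL = FALSE, super = TRUE)
              else Matrix::update(ch, As)
        .luxnet_cache[[cache_key]] <- ch
        as.numeric(Matrix::solve(ch, b, system = "A"))
      } else {
        as.numeric(Matrix::solve(A, b))
      }
    }, error = function(e)
      stop("resistor network solve failed (disconnected component?): ",
           conditionMessage(e), call. = FALSE))
    res <- as.numeric(A %*% v_int - b)
    scale <- max(abs(b), max(abs(v_int)) * max(dii), .Machine$double.xmin)
    if (max(abs(res)) > tol * scale)
      stop(sprintf("Kirchhoff residual %.3e exceeds tolerance", max(abs(res)) / scale),
           call. = FALSE)
    v_full[interior] <- v_int
  }
  # total current leaving the source contact (includes any direct
  # source-sink edges, for which the other endpoint sits at potential 0)
  at_src <- (ri == 1L) != (rj == 1L)
  other <- ifelse(role[ei] == 1L, ej, ei)[at_src]
  sum(g[at_src] * (V - v_full[other]))
}

#' Per-step total current of a colony state
#'
#' Convenience wrapper running phase (ii): assemble the resistor network from
#' the current state and links and solve it for each requested Hill number.
#'
#' @inheritParams assemble_network
#' @return numeric vector of total currents, one per `gamma`.
#' @export
rrn_readout <- function(state, links, config, gamma = config$hill_gamma) {
  net <- assemble_network(state, links, config, gamma)
  vapply(seq_along(gamma), function(gi) solve_current(net, gi), numeric(1))
}
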