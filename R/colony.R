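#' Inoculate the lattice
#'
#' Places `floor(initial_fill * grid_side^2)` unit c-charges on distinct sites
#' chosen uniformly at random.  Five percent occupancy is the threshold density
#' at which colony development starts.
#'
#' @param config a [qs_config()].
#' @return a `colony_state`: list with integer charge matrices `q` (current)
#'   and `q_prev` (previous iteration, equal to `q` at t = 0) and counter `t`.
#' @export
initialize_colony <- function(config) {
  validate_qs_config(config)
  L <- config$grid_side
  n_init <- floor(config$initial_fill * L^2)
  sites <- sample.int(L^2, n_init)
  q <- matrix(0L, L, L)
  q[sites] <- 1L
  state <- list(q = q, q_prev = q, t = 0L)
  class(state) <- "colony_state"
  state
}

#' Long-range potential, per-site energy and system energy
#'
#' The c-charges interact through a Coulomb-like potential: the potential at a
#' site is the sum of `Q(r) / dist` over every other site, with Euclidean
#' distance in lattice units and the self-term excluded.  The per-site energy
#' is `e(r) = Q(r) v(r)`; summing it double-counts each pair, so the pairwise
#' interaction energy (which sets the Boltzmann temperature of link opening)
#' is `beta_inv = energy_total / 2`.
#'
#' @param state a `colony_state`.
#' @return list with fields `v`, `e` (matrices), `energy_total`, `beta_inv`.
#' @export
compute_potential <- function(state) {
  q <- state$q
  L <- nrow(q)
  K <- inverse_distance_kernel(L)
  v <- matrix(as.vector(K %*% as.numeric(q)), L, L)
  e <- q * v
  energy_total <- sum(e)
  field <- list(v = v, e = e, energy_total = energy_total,
                beta_inv = energy_total / 2)
  class(field) <- "potential_field"
  field
}

#' Open autoinducer exchange channels
#'
#' Every alive cell (donor) considers each alive neighbor at strictly lower
#' potential (receiver) and opens a directed channel with Boltzmann-like
#' probability `min(1, exp(-beta * (e_donor - e_receiver)))`, where
#' `1/beta` is the pairwise interaction energy of the whole system.  With
#' fewer than two interacting charges `beta_inv = 0`; the exponent is then
#' treated as 0 and every candidate channel opens (probability 1).
#'
#' Channels live for one iteration and are rebuilt from scratch each step.
#'
#' @param state a `colony_state`.
#' @param field the [compute_potential()] field of `state`.
#' @param config a [qs_config()].
#' @return a `link_set`: list with integer vectors `donor`, `receiver` (site
#'   indices) and `n_sites`.
#' @export
open_links <- function(state, field, config) {
  L <- nrow(state$q)
  geom <- lattice_geometry(L, config$neighborhood)
  qv <- as.integer(state$q)
  vv <- as.numeric(field$v)
  ev <- as.numeric(field$e)
  donors <- which(qv > 0L)
  d_all <- integer(0); r_all <- integer(0); p_all <- numeric(0)
  if (length(donors)) {
    beta <- if (field$beta_inv > 0) 1 / field$beta_inv else 0
    for (s in seq_len(geom$k)) {
      nb <- geom$nbr[donors, s]
      ok <- !is.na(nb)
      ok[ok] <- qv[nb[ok]] > 0L & vv[nb[ok]] < vv[donors[ok]]
      if (!any(ok)) next
      d <- donors[ok]; r <- nb[ok]
      p <- pmin(1, exp(-beta * (ev[d] - ev[r])))
      d_all <- c(d_all, d); r_all <- c(r_all, r); p_all <- c(p_all, p)
    }
  }
  if (length(d_all)) {
    keep <- stats::runif(length(d_all)) < p_all
    d_all <- d_all[keep]; r_all <- r_all[keep]
  }
  links <- list(donor = d_all, receiver = r_all, n_sites = geom$n)
  class(links) <- "link_set"
  links
}

#' Charge update through open channels
#'
#' Each receiver with `k` incident channels (channels touching it, in either
#' role) gains `floor(sigma * k / N)` units of c-charge, capped at `q_max`;
#' a site at `q_max` is doomed to die in the spatial-evolution phase.
#' Non-receivers are unchanged: channel opening costs the donor nothing.
#'
#' @param state a `colony_state`.
#' @param links a `link_set` built from `state`.
#' @param config a [qs_config()].
#' @return the updated `colony_state`.
#' @export
update_charges <- function(state, links, config) {
  if (length(links$receiver)) {
    inc_count <- tabulate(c(links$donor, links$receiver), nbins = links$n_sites)
    rec <- unique(links$receiver)
    gain <- as.integer(floor(config$sigma * inc_count[rec] / config$eq3_norm))
    state$q[rec] <- pmin(state$q[rec] + gain, config$q_max)
  }
  state
}

#' Colony spatial evolution: death, reproduction, migration
#'
#' Applied once per iteration, after the charge update:
#' \describe{
#'   \item{death}{every site whose charge reached `q_max` is emptied; its site
#'     cannot be recolonised until the next iteration.}
#'   \item{reproduction}{each alive cell with `Q >= q_rep` and at least one
#'     empty neighbor transfers `floor(Q/2)` to the empty neighbor of lowest
#'     potential (ties broken uniformly at random), keeping the remainder.}
#'   \item{migration}{each cell with `Q = 1` moves its unit charge to the
#'     empty neighbor of lowest potential.}
#' }
#' Cells act in a random order drawn from the run's stream; each cell sees the
#' lattice as left by the cells before it.  Reproduction and migration
#' conserve total charge; only death destroys it.
#'
#' @param state a `colony_state`.
#' @param field potential field of `state` (after the charge update).
#' @param config a [qs_config()].
#' @return the evolved `colony_state`, with attribute `died_charge`: the total
#'   charge removed by deaths this step.
#' @export
evolve_colony <- function(state, field, config) {
  L <- nrow(state$q)
  geom <- lattice_geometry(L, config$neighborhood)
  q <- as.integer(state$q)
  vv <- as.numeric(field$v)

  dying <- which(q >= config$q_max)
  died_charge <- sum(q[dying])
  q[dying] <- 0L
  blocked <- logical(geom$n)
  blocked[dying] <- TRUE                       # no recolonisation within the step

  actors <- which(q > 0L)
  if (length(actors) > 1L) actors <- sample(actors)
  for (s in actors) {
    qs <- q[s]
    if (qs < 1L) next
    nb <- geom$nbr[s, ]
    nb <- nb[!is.na(nb)]
    empt <- nb[q[nb] == 0L & !blocked[nb]]
    if (!length(empt)) next
    if (qs >= config$q_rep) {
      tgt <- pick_lowest(empt, vv)
      m <- qs %/% 2L
      q[tgt] <- m
      q[s] <- qs - m
    } else if (qs == 1L) {
      tgt <- pick_lowest(empt, vv)
      q[tgt] <- 1L
      q[s] <- 0L
    }
  }
  state$q <- matrix(q, L, L)
  attr(state, "died_charge") <- died_charge
  state
}

# lowest-potential site among candidates, ties broken uniformly at random
pick_lowest <- function(cand, vv) {
  if (length(cand) == 1L) return(cand)
  vmin <- min(vv[cand])
  best <- cand[vv[cand] <= vmin]
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}
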