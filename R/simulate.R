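#' Advance the simulation by one iteration
#'
#' One iteration applies three phases: (i) compute the long-range potential,
#' open channels, and update the c-charges; (ii) read the colony out as a
#' random resistor network and record the total current; (iii) evolve the
#' colony spatially (death, reproduction, migration).  The Hill drive of
#' phase (ii) keeps one step of memory: it averages the charges at the
#' charge-update point of this iteration and of the previous one.
#'
#' @param state a `colony_state`.
#' @param config a [qs_config()].
#' @param gamma Hill number(s) for the readout, or `NULL` to skip phase (ii)
#'   (the record then carries `NA` currents).
#' @return list with `state` (the successor) and `record` (one-row data.frame:
#'   `step, total_charge, occupancy, energy, charge_pre_evolve, died_charge`)
#'   plus `current`, the per-gamma current vector.
#' @export
qs_step <- function(state, config, gamma = config$hill_gamma) {
  L <- config$grid_side
  cache_key <- sprintf("chol_%d_%d", L, config$neighborhood)

  # phase (i): potential, links, charge update
  field <- compute_potential(state)
  links <- open_links(state, field, config)
  prev_rrn <- state$q                   # charges at the previous update point
  state <- update_charges(state, links, config)

  # phase (ii): resistor-network readout
  current <- if (is.null(gamma)) numeric(0) else {
    w_state <- list(q = state$q, q_prev = prev_rrn)
    net <- assemble_network(w_state, links, config, gamma)
    vapply(seq_along(gamma),
           function(gi) solve_current(net, gi, cache_key = cache_key),
           numeric(1))
  }

  # phase (iii): spatial evolution under the post-update field
  field2 <- compute_potential(state)
  charge_pre <- sum(state$q)
  state <- evolve_colony(state, field2, config)
  died <- attr(state, "died_charge")

  state$q_prev <- prev_rrn
  state$t <- state$t + 1L
  record <- data.frame(step = state$t,
                       total_charge = sum(state$q),
                       occupancy = sum(state$q > 0L),
                       energy = field2$energy_total,
                       charge_pre_evolve = charge_pre,
                       died_charge = died)
  list(state = state, record = record, current = current)
}

#' Run the lattice quorum-sensing simulation
#'
#' Inoculates the lattice and iterates [qs_step()] for `n_steps` iterations,
#' collecting per-step observables.  All randomness flows from `config$seed`,
#' so identical configurations give bit-identical traces.
#'
#' @param config a [qs_config()].
#' @param gamma Hill number(s) for the current readout.  Because the colony
#'   dynamics do not depend on the readout, a single run can be read out at
#'   many Hill numbers at once (one extra linear solve per value per step).
#'   `NULL` skips the readout entirely (fast runs for charge observables).
#' @param snapshots if `TRUE`, keep the charge lattice of every step.
#' @return a `qs_trace`: data.frame with columns `step, total_charge,
#'   occupancy, energy, charge_pre_evolve, died_charge, current` (current of
#'   the first gamma), plus attributes `current` (matrix steps x gamma),
#'   `gamma`, `config`, `final_state`, and optionally `snapshots`.
#' @export
#' @examples
#' tr <- run_simulation(qs_config(grid_side = 15, q_max = 20, n_steps = 30,
#'                                seed = 7), gamma = 2)
#' summary(tr)
run_simulation <- function(config, gamma = config$hill_gamma, snapshots = FALSE) {
  validate_qs_config(config)
  set.seed(config$seed)
  state <- initialize_colony(config)
  n <- config$n_steps
  recs <- vector("list", n)
  cur <- matrix(NA_real_, n, length(gamma))
  snaps <- if (snapshots) vector("list", n) else NULL
  for (i in seq_len(n)) {
    out <- qs_step(state, config, gamma)
    state <- out$state
    recs[[i]] <- out$record
    if (length(out$current)) cur[i, ] <- out$current
    if (snapshots) snaps[[i]] <- state$q
  }
  tr <- do.call(rbind, recs)
  tr$current <- if (ncol(cur)) cur[, 1] else NA_real_
  attr(tr, "current") <- cur
  attr(tr, "gamma") <- if (is.null(gamma)) numeric(0) else as.numeric(gamma)
  attr(tr, "config") <- config
  attr(tr, "final_state") <- state
  if (snapshots) attr(tr, "snapshots") <- snaps
  class(tr) <- c("qs_trace", "data.frame")
  tr
}

#' @export
print.qs_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Lattice quorum-sensing trace: %d steps on a %dx%d grid (q_max = %d, seed = %d)\n",
              nrow(x), cfg$grid_side, cfg$grid_side, cfg$q_max, cfg$seed))
  g <- attr(x, "gamma")
  if (length(g)) cat("  readout Hill number(s):", paste(g, collapse = ", "), "\n")
  cat(sprintf("  final total charge %d, occupancy %d\n",
              x$total_charge[nrow(x)], x$occupancy[nrow(x)]))
  invisible(x)
}

#' @export
summary.qs_trace <- function(object, ...) {
  on <- tryCatch(onset_time(object), error = function(e) NA_integer_)
  out <- list(
    steps = nrow(object),
    onset = on,
    stationary_charge = if (is.na(on)) NA_real_ else
      mean(object$total_charge[on:nrow(object)]),
    final_occupancy = object$occupancy[nrow(object)],
    gamma = attr(object, "gamma")
  )
  class(out) <- "summary.qs_trace"
  out
}

#' @export
print.summary.qs_trace <- function(x, ...) {
  cat(sprintf("steps: %d   stationarity onset: %s\n", x$steps,
              ifelse(is.na(x$onset), "not reached", x$onset)))
  if (!is.na(x$onset))
    cat(sprintf("stationary mean total charge: %.1f\n", x$stationary_charge))
  cat(sprintf("final occupancy: %d sites\n", x$final_occupancy))
  invisible(x)
}

#' @export
plot.qs_trace <- function(x, which = c("charge", "current"), ...) {
  which <- match.arg(which)
  if (which == "charge") {
    graphics::plot(x$step, x$total_charge, type = "l", xlab = "iteration",
                   ylab = "total c-charge", ...)
  } else {
    graphics::plot(x$step, x$current, type = "l", xlab = "iteration",
                   ylab = "total current (arb. units)", ...)
  }
  invisible(x)
}

#' Write / read a trace as CSV
#'
#' The CSV carries the per-step records (`step, total_charge, occupancy,
#' energy, current`); a `#`-prefixed header line echoes the fully-resolved
#' configuration as JSON so a run can be reproduced from its own output.
#'
#' @param trace a `qs_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  cfg <- attr(trace, "config")
  hdr <- paste0("# config: ", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(trace[, c("step", "total_charge", "occupancy", "energy", "current")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param path CSV file written by [write_trace()].
#' @return `read_trace`: a `qs_trace` (records and config; lattice state is
#'   not stored in the CSV).
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  cfg <- NULL
  if (startsWith(first, "# config: ")) {
    cfg <- do.call(qs_config, jsonlite::fromJSON(sub("^# config: ", "", first)))
  }
  tr <- utils::read.csv(path, comment.char = "#")
  attr(tr, "config") <- cfg
  attr(tr, "gamma") <- if (!is.null(cfg)) cfg$hill_gamma else numeric(0)
  attr(tr, "current") <- matrix(tr$current, ncol = 1)
  class(tr) <- c("qs_trace", "data.frame")
  tr
}
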