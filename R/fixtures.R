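#' Deterministic small test objects
#'
#' Builds the small instances used throughout the test suite and examples:
#' \describe{
#'   \item{`"tiny-colony"`}{a 10x10 `colony_state` with a random sprinkle of
#'     charges (seeded), suitable for brute-force potential checks.}
#'   \item{`"linked-grid"`}{a 2x2 `resistor_network` with two resistors (2 and
#'     3 units) bridging the contact rows; exact current `5/6` at unit
#'     potential.}
#'   \item{`"synthetic-trace"`}{a `qs_trace`-shaped object with a linear ramp
#'     to a plateau at step 40 of 200 and a planted period-20 oscillation,
#'     plus a current series with known stationary mean 2.0.}
#'   \item{`"synthetic-panel"`}{a relative-bioluminescence panel generated
#'     from known weights (0.4, 0.2, 0.1), alpha = 3, on a synthetic smooth
#'     BA curve; ground truth attached as attributes.}
#' }
#'
#' @param kind one of the kinds above.
#' @param seed integer seed for the stochastic fixtures.
#' @return the fixture object; see Details.
#' @export
make_fixture <- function(kind = c("tiny-colony", "linked-grid",
                                  "synthetic-trace", "synthetic-panel"),
                         seed = 42L) {
  kind <- match.arg(kind)
  switch(kind,
    "tiny-colony" = {
      set.seed(seed)
      L <- 10L
      q <- matrix(0L, L, L)
      occ <- sample.int(L^2, 18L)
      q[occ] <- sample(1:5, 18L, replace = TRUE)
      structure(list(q = q, q_prev = q, t = 0L), class = "colony_state")
    },
    "linked-grid" = {
      structure(list(n_nodes = 4L,
                     edges = data.frame(i = c(1L, 3L), j = c(2L, 4L), d = c(1, 1)),
                     R = matrix(c(2, 3), 2L, 1L),
                     gamma = NA_real_,
                     source_nodes = c(1L, 3L),
                     sink_nodes = c(2L, 4L),
                     applied_potential = 1),
                class = "resistor_network")
    },
    "synthetic-trace" = {
      n <- 200L
      onset_true <- 40L
      plateau <- 1000
      ramp <- seq(0, plateau, length.out = onset_true)
      osc <- plateau + 50 * sin(2 * pi * (1:(n - onset_true)) / 20)
      total <- c(ramp, osc)
      cur <- c(seq(0, 2, length.out = onset_true),
               2 + 0.1 * sin(2 * pi * (1:(n - onset_true)) / 20))
      tr <- data.frame(step = seq_len(n), total_charge = total,
                       occupancy = NA_integer_, energy = NA_real_,
                       charge_pre_evolve = NA_real_, died_charge = NA_real_,
                       current = cur)
      attr(tr, "current") <- matrix(cur, ncol = 1L)
      attr(tr, "gamma") <- 5
      class(tr) <- c("qs_trace", "data.frame")
      attr(tr, "planted") <- list(onset = onset_true, period = 20,
                                  current_mean = 2.0)
      tr
    },
    "synthetic-panel" = {
      w <- ai_weights(0.4, 0.2, 0.1)
      truth <- bl_model(k = 1, alpha = 3, weights = w)
      gam <- seq(0.05, 1.2, by = 0.05)
      curve <- data.frame(gamma = gam,
                          ba = 1 / (1 + exp(-6 * (gam - 0.45))),
                          se = 0)
      class(curve) <- c("ba_curve", "data.frame")
      mutants <- c("HAI-1+AI-2", "HAI-1+CAI-1", "AI-2+CAI-1",
                   "HAI-1", "AI-2", "CAI-1")
      bl <- vapply(mutants,
                   function(m) predict_mutant_bl(truth, curve, m)$rel_bl,
                   numeric(1))
      panel <- data.frame(mutant = mutants, bl = unname(bl))
      attr(panel, "truth") <- truth
      attr(panel, "curve") <- curve
      panel
    })
}
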