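test_that("inoculation seeds the exact occupancy with unit charges", {
  cfg <- qs_config(seed = 11)
  set.seed(cfg$seed)
  st <- initialize_colony(cfg)
  expect_equal(sum(st$q == 1L), 125L)     # floor(0.05 * 50^2)
  expect_equal(sum(st$q), 125L)
  expect_identical(st$q_prev, st$q)
  expect_identical(st$t, 0L)

  set.seed(cfg$seed)
  st2 <- initialize_colony(cfg)
  expect_identical(st$q, st2$q)           # same seed, same inoculum

  # a grid too small to seed a single cell is below the development threshold
  expect_error(qs_config(grid_side = 3, initial_fill = 0.05),
               "below the development threshold")
})

test_that("long-range potential matches closed forms and the brute-force sum", {
  L <- 9L
  q <- matrix(0L, L, L)
  q[1, 1] <- 1L
  f <- compute_potential(list(q = q))
  expect_equal(f$v[4, 1], 1 / 3)          # distance 3 from the single charge
  expect_equal(f$v[1, 1], 0)              # self-term excluded
  expect_equal(f$beta_inv, 0)

  # empty lattice
  f0 <- compute_potential(list(q = matrix(0L, 5, 5)))
  expect_true(all(f0$v == 0))
  expect_equal(f0$energy_total, 0)

  # two unit charges at distance 1
  q2 <- matrix(0L, 5, 5); q2[2, 2] <- 1L; q2[3, 2] <- 1L
  f2 <- compute_potential(list(q = q2))
  expect_equal(f2$e[2, 2], 1)
  expect_equal(f2$e[3, 2], 1)
  expect_equal(f2$energy_total, 2)
  expect_equal(f2$beta_inv, 1)

  # random occupancies against the independent double loop
  for (seed in 1:3) {
    set.seed(seed)
    q <- matrix(sample(0:4, 100, replace = TRUE, prob = c(.6, .1, .1, .1, .1)), 10, 10)
    f <- compute_potential(list(q = q))
    vb <- brute_force_potential(q)
    expect_lt(max(abs(f$v - vb)) / max(vb), 1e-10)
    expect_equal(f$energy_total, 2 * f$beta_inv)
    expect_equal(f$energy_total, sum(q * vb), tolerance = 1e-12)
  }
})

test_that("channels open only downhill between alive cells, at the Boltzmann rate", {
  cfg <- tiny_config()
  set.seed(1)
  st <- make_fixture("tiny-colony", seed = 3)
  f <- compute_potential(st)
  for (i in 1:5) {
    links <- open_links(st, f, cfg)
    if (!length(links$donor)) next
    expect_true(all(st$q[links$donor] > 0))
    expect_true(all(st$q[links$receiver] > 0))
    expect_true(all(f$v[links$receiver] < f$v[links$donor]))
    # neighbor pairs only (Moore)
    dr <- abs((links$donor - 1) %% 10 - (links$receiver - 1) %% 10)
    dc <- abs((links$donor - 1) %/% 10 - (links$receiver - 1) %/% 10)
    expect_true(all(dr <= 1 & dc <= 1))
  }
})

test_that("channel opening frequency matches its Boltzmann probability", {
  cfg <- tiny_config()
  st <- make_fixture("tiny-colony", seed = 3)
  f <- compute_potential(st)
  # enumerate candidates and their analytic probabilities
  set.seed(99)
  n_trials <- 10000L
  counts <- new.env()
  for (t in seq_len(n_trials)) {
    links <- open_links(st, f, cfg)
    if (length(links$donor)) {
      keys <- paste(links$donor, links$receiver)
      for (k in keys) assign(k, (get0(k, counts, ifnotfound = 0)) + 1, counts)
    }
  }
  beta <- 1 / f$beta_inv
  keys <- ls(counts)
  expect_gt(length(keys), 3)
  for (k in keys) {
    dr <- as.integer(strsplit(k, " ")[[1]])
    p <- min(1, exp(-beta * (f$e[dr[1]] - f$e[dr[2]])))
    emp <- get(k, counts) / n_trials
    se <- sqrt(max(p * (1 - p), 1e-12) / n_trials)
    expect_lt(abs(emp - p), max(3 * se, 1e-9))
  }
})

test_that("degenerate interaction energy opens every candidate channel", {
  # a single charge: beta_inv = 0, exponent treated as 0, probability 1 --
  # but a lone cell has no lower-potential alive neighbor, so no channels.
  cfg <- tiny_config()
  q <- matrix(0L, 12, 12); q[5, 5] <- 1L
  st <- list(q = q, q_prev = q, t = 0L)
  f <- compute_potential(st)
  expect_equal(f$beta_inv, 0)
  set.seed(1)
  links <- open_links(st, f, cfg)
  expect_length(links$donor, 0)
})

test_that("charge update applies the floored increment to receivers only", {
  cfg <- qs_config(grid_side = 10, sigma = 50, eq3_norm = 100, n_steps = 1)
  q <- matrix(1L, 10, 10)
  st <- list(q = q, q_prev = q, t = 0L)
  # ten channels incident to receiver site 1
  links <- structure(list(donor = rep(2:11, 1), receiver = rep(1L, 10),
                          n_sites = 100L), class = "link_set")
  st2 <- update_charges(st, links, cfg)
  expect_equal(st2$q[1], 1L + 5L)         # floor(50 * 10 / 100) = 5
  expect_equal(st2$q[12], 1L)             # non-receiver unchanged
  # donors are unchanged even though their channels are counted
  expect_equal(st2$q[2], 1L)

  # increments below one unit floor to zero
  cfg2 <- qs_config(grid_side = 10, sigma = 9, eq3_norm = 100, n_steps = 1)
  links1 <- structure(list(donor = 2L, receiver = 1L, n_sites = 100L),
                      class = "link_set")
  expect_equal(update_charges(st, links1, cfg2)$q[1], 1L)
  # no channels at all
  links0 <- structure(list(donor = integer(0), receiver = integer(0),
                           n_sites = 100L), class = "link_set")
  expect_identical(update_charges(st, links0, cfg)$q, st$q)
  # cap at q_max
  cfg3 <- qs_config(grid_side = 10, sigma = 90, eq3_norm = 100, q_max = 4,
                    q_rep = 2, n_steps = 1)
  st3 <- update_charges(st, links, cfg3)
  expect_equal(st3$q[1], 4L)
})

test_that("spatial evolution reproduces, migrates and kills as specified", {
  cfg <- qs_config(grid_side = 9, q_max = 10, n_steps = 1)
  mkstate <- function(q) list(q = q, q_prev = q, t = 0L)
  # isolated cell with Q = 4: neighbor gets 2, parent keeps 2
  q <- matrix(0L, 9, 9); q[5, 5] <- 4L
  set.seed(2)
  st <- evolve_colony(mkstate(q), compute_potential(mkstate(q)), cfg)
  expect_equal(sum(st$q), 4L)
  expect_equal(st$q[5, 5], 2L)
  expect_equal(sum(st$q == 2L), 2L)

  # odd split: transfer floor(5/2) = 2, keep 3
  q <- matrix(0L, 9, 9); q[5, 5] <- 5L
  set.seed(2)
  st <- evolve_colony(mkstate(q), compute_potential(mkstate(q)), cfg)
  expect_equal(sort(st$q[st$q > 0]), c(2L, 3L))

  # a cell at q_max dies
  q <- matrix(0L, 9, 9); q[5, 5] <- 10L
  st <- evolve_colony(mkstate(q), compute_potential(mkstate(q)), cfg)
  expect_equal(sum(st$q), 0L)
  expect_equal(attr(st, "died_charge"), 10L)

  # blocked migration: Q = 1 surrounded by occupied sites stays put
  q <- matrix(0L, 9, 9); q[4:6, 4:6] <- 1L
  # fill the whole lattice so nobody can move
  q[, ] <- 1L
  set.seed(2)
  st <- evolve_colony(mkstate(q), compute_potential(mkstate(q)), cfg)
  expect_identical(st$q, q)
})

test_that("phase-three bookkeeping conserves charge up to deaths", {
  cfg <- tiny_config()
  tr <- run_simulation(cfg, gamma = NULL)
  expect_true(all(tr$total_charge == tr$charge_pre_evolve - tr$died_charge))
})

test_that("a step only adds charge before the evolution phase", {
  cfg <- qs_config(seed = 3, n_steps = 1)
  set.seed(cfg$seed)
  st <- initialize_colony(cfg)
  out <- qs_step(st, cfg, gamma = NULL)
  expect_gte(out$record$charge_pre_evolve, 125)
})

test_that("the empty lattice is absorbing", {
  cfg <- tiny_config()
  q <- matrix(0L, 12, 12)
  st <- list(q = q, q_prev = q, t = 0L)
  set.seed(1)
  out <- qs_step(st, cfg, gamma = 2)
  expect_equal(out$record$total_charge, 0)
  expect_equal(sum(out$state$q), 0L)
  # the dead-state current is the all-background-resistance floor
  empty_net <- assemble_network(st, structure(list(donor = integer(0),
                                                   receiver = integer(0),
                                                   n_sites = 144L),
                                              class = "link_set"), cfg, 2)
  expect_equal(out$current, solve_current(empty_net), tolerance = 1e-10)
})

test_that("identical configurations give bit-identical traces", {
  cfg <- tiny_config()
  t1 <- run_simulation(cfg, gamma = 2)
  t2 <- run_simulation(cfg, gamma = 2)
  expect_identical(t1$total_charge, t2$total_charge)
  expect_identical(attr(t1, "current"), attr(t2, "current"))
  expect_identical(attr(t1, "final_state")$q, attr(t2, "final_state")$q)
})

test_that("charges stay within bounds over a full run", {
  cfg <- qs_config(grid_side = 20, q_max = 15, n_steps = 60, seed = 2)
  tr <- run_simulation(cfg, gamma = NULL, snapshots = TRUE)
  for (q in attr(tr, "snapshots")) {
    expect_true(all(q >= 0L))
    expect_true(all(q <= cfg$q_max))
  }
})
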