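# Mapping the asymptotic network current (bioluminescence analogue, BA) to
# relative bioluminescence of V. harveyi autoinducer mutants.  Each of the
# three autoinducers (HAI-1, AI-2, CAI-1) carries a cooperative weight
# gamma_i; a strain expressing the subset S responds with Hill number
# gamma = sum_{i in S} gamma_i, and its light output follows the power law
# BL = k * BA(gamma)^alpha.

AI_NAMES <- c("HAI-1", "AI-2", "CAI-1")

#' Per-autoinducer cooperative weights
#'
#' @param hai1,ai2,cai1 positive cooperative weights of the three
#'   V. harveyi autoinducers.
#' @return named numeric vector of class `ai_weights`.
#' @export
ai_weights <- function(hai1, ai2, cai1) {
  w <- c("HAI-1" = as.numeric(hai1), "AI-2" = as.numeric(ai2),
         "CAI-1" = as.numeric(cai1))
  if (any(w <= 0)) stop("cooperative weights must be positive", call. = FALSE)
  class(w) <- "ai_weights"
  w
}

#' Published cooperative weights for V. harveyi panels
#'
#' Cooperative weights fitted to relative-bioluminescence panels of
#' V. harveyi autoinducer mutants grown in liquid culture and on a solid
#' hydroxyapatite (HA) substrate, together with the shared power-law exponent
#' alpha = 3.0 and the normalisations k = 2.6 (liquid) and k = 0.03 (HA).
#'
#' @param substrate `"liquid"` or `"HA"`.
#' @return a `bl_model` with the published weights, alpha and k.
#' @export
vh_model <- function(substrate = c("liquid", "HA")) {
  substrate <- match.arg(substrate)
  if (substrate == "liquid")
    bl_model(k = 2.6, alpha = 3.0, weights = ai_weights(0.40, 0.22, 0.13))
  else
    bl_model(k = 0.03, alpha = 3.0, weights = ai_weights(0.81, 1.0, 0.37))
}

#' Observed relative-bioluminescence reductions of two-component mutants
#'
#' Percent reduction in light output of the three two-component mutants
#' (each lacking one autoinducer) relative to the wild type, as reported for
#' liquid culture and for growth on hydroxyapatite.
#'
#' @param substrate `"liquid"` or `"HA"`.
#' @return data.frame with columns `mutant` (the expressed set) and
#'   `reduction_pct`.
#' @export
vh_observed_reductions <- function(substrate = c("liquid", "HA")) {
  substrate <- match.arg(substrate)
  if (substrate == "liquid")
    data.frame(mutant = c("HAI-1+AI-2", "HAI-1+CAI-1", "AI-2+CAI-1"),
               reduction_pct = c(83, 96, 99))
  else
    data.frame(mutant = c("HAI-1+AI-2", "AI-2+CAI-1", "HAI-1+CAI-1"),
               reduction_pct = c(60, 96, 99))
}

#' Parse a mutant specification
#'
#' A mutant is the non-empty set of autoinducers it expresses, written either
#' as a character vector or a `+`-separated string such as `"HAI-1+AI-2"`.
#'
#' @param mutant character vector or `+`-separated string.
#' @return canonical character vector (subset of HAI-1, AI-2, CAI-1).
#' @export
parse_mutant <- function(mutant) {
  s <- unlist(strsplit(mutant, "+", fixed = TRUE))
  s <- trimws(s)
  bad <- setdiff(s, AI_NAMES)
  if (length(bad))
    stop("unknown autoinducer(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!length(s))
    stop("dark strain: a luminous mutant expresses at least one autoinducer",
         call. = FALSE)
  unique(s)
}

#' Hill number of a mutant
#'
#' The cooperative weights combine additively ("democratically"): the Hill
#' number of a strain is the sum of the weights of the autoinducers it
#' expresses.
#'
#' @param weights an [ai_weights()] vector.
#' @param mutant a mutant specification (see [parse_mutant()]).
#' @return the Hill number gamma of the strain.
#' @export
gamma_for_mutant <- function(weights, mutant) {
  s <- parse_mutant(mutant)
  sum(unclass(weights)[s])
}

#' Bioluminescence model
#'
#' @param k positive normalisation of the power law `BL = k * BA^alpha`.
#' @param alpha positive exponent.
#' @param weights an [ai_weights()] vector.
#' @param fit optional fitting diagnostics (kept by [fit_bl_model()]).
#' @return object of class `bl_model`.
#' @export
bl_model <- function(k, alpha, weights, fit = NULL) {
  stopifnot(k > 0, alpha > 0, inherits(weights, "ai_weights"))
  structure(list(k = as.numeric(k), alpha = as.numeric(alpha),
                 weights = weights, fit = fit),
            class = "bl_model")
}

#' @export
print.bl_model <- function(x, ...) {
  cat("Power-law bioluminescence model: BL = k * BA^alpha\n")
  cat(sprintf("  k = %g, alpha = %g\n", x$k, x$alpha))
  cat(sprintf("  cooperative weights: HAI-1 = %.3g, AI-2 = %.3g, CAI-1 = %.3g\n",
              x$weights[["HAI-1"]], x$weights[["AI-2"]], x$weights[["CAI-1"]]))
  if (!is.null(x$fit))
    cat(sprintf("  fit: residual norm %.4g (%d observations)\n",
                x$fit$residual_norm, x$fit$n_obs))
  invisible(x)
}

#' @export
coef.bl_model <- function(object, ...) {
  c(k = object$k, alpha = object$alpha,
    gamma_hai1 = object$weights[["HAI-1"]],
    gamma_ai2 = object$weights[["AI-2"]],
    gamma_cai1 = object$weights[["CAI-1"]])
}

#' @export
residuals.bl_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model was not fitted", call. = FALSE)
  object$fit$residuals
}

#' Bioluminescence from the analogue current
#'
#' @param ba non-negative asymptotic current (bioluminescence analogue).
#' @param model a [bl_model()].
#' @return `k * ba^alpha`.
#' @export
bl_from_ba <- function(ba, model) {
  stopifnot(all(ba >= 0))
  model$k * ba^model$alpha
}

#' Simulate the BA(gamma) curve
#'
#' Runs the simulator once per seed, reading the resistor network out at
#' every requested Hill number (the colony dynamics are independent of the
#' readout, so one run serves the whole gamma grid), and averages the
#' per-run asymptotic currents.  The standard error is across seeds.
#'
#' @param gammas strictly increasing Hill numbers.
#' @param config base configuration (its `seed` starts the seed sequence and
#'   its `hill_gamma` is ignored).
#' @param n_seeds number of independent runs.
#' @return a `ba_curve`: data.frame `gamma, ba, se, n_seeds` with a monotone
#'   interpolant; see [predict.ba_curve()].
#' @export
ba_curve <- function(gammas, config, n_seeds = 5L) {
  gammas <- as.numeric(gammas)
  if (is.unsorted(gammas, strictly = TRUE))
    stop("gammas must be strictly increasing", call. = FALSE)
  per_run <- matrix(NA_real_, n_seeds, length(gammas))
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + s - 1L
    tr <- run_simulation(cfg, gamma = gammas)
    cur <- attr(tr, "current")
    onset <- onset_time(tr)
    per_run[s, ] <- colMeans(cur[onset:nrow(cur), , drop = FALSE])
  }
  ba <- colMeans(per_run)
  se <- if (n_seeds > 1L) apply(per_run, 2L, stats::sd) / sqrt(n_seeds) else
    rep(0, length(gammas))
  out <- data.frame(gamma = gammas, ba = ba, se = se, n_seeds = n_seeds)
  attr(out, "per_run") <- per_run
  attr(out, "config") <- config
  class(out) <- c("ba_curve", "data.frame")
  out
}

#' Interpolate a BA curve
#'
#' Monotone piecewise-cubic interpolation of the simulated BA values over
#' gamma; requests outside the simulated range are an error (the curve never
#' extrapolates).  Standard errors are interpolated linearly.
#'
#' @param object a `ba_curve` (or a data.frame with `gamma`, `ba`, and
#'   optionally `se` columns, e.g. a synthetic curve).
#' @param gamma Hill numbers at which to evaluate.
#' @param se if `TRUE`, return a list with `ba` and `se`.
#' @param ... unused.
#' @return interpolated BA values (or a list when `se = TRUE`).
#' @export
predict.ba_curve <- function(object, gamma, se = FALSE, ...) {
  rng <- range(object$gamma)
  if (any(gamma < rng[1L] | gamma > rng[2L]))
    stop(sprintf("gamma outside the simulated range [%g, %g]; extend the curve",
                 rng[1L], rng[2L]), call. = FALSE)
  f <- stats::splinefun(object$gamma, object$ba, method = "monoH.FC")
  ba <- f(gamma)
  if (!se) return(ba)
  s <- if (!is.null(object$se))
    stats::approx(object$gamma, object$se, xout = gamma)$y else rep(0, length(gamma))
  list(ba = ba, se = s)
}

#' @export
print.ba_curve <- function(x, ...) {
  cat(sprintf("BA(gamma) curve: %d gamma values in [%g, %g], %d seed(s)\n",
              nrow(x), min(x$gamma), max(x$gamma), x$n_seeds[1L]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.ba_curve <- function(x, ...) {
  graphics::plot(x$gamma, x$ba, type = "b", pch = 16, xlab = "Hill number",
                 ylab = "BA (arb. units)", ...)
  graphics::arrows(x$gamma, x$ba - x$se, x$gamma, x$ba + x$se,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Relative bioluminescence of a mutant
#'
#' Relative light output of a mutant (wild type = 100 percent), obtained from
#' the interpolated BA curve through the additive weights and the power law.
#' Uncertainty is propagated from the BA standard errors by the delta method.
#'
#' @param model a [bl_model()].
#' @param curve a `ba_curve`.
#' @param mutant mutant specification.
#' @return list with `rel_bl` (percent) and `se`.
#' @export
predict_mutant_bl <- function(model, curve, mutant) {
  g_wt <- sum(unclass(model$weights))
  g_m <- gamma_for_mutant(model$weights, mutant)
  p <- predict(curve, c(g_m, g_wt), se = TRUE)
  a <- model$alpha
  ratio <- p$ba[1L] / p$ba[2L]
  rel <- 100 * ratio^a
  dd_m <- 100 * a * ratio^(a - 1) / p$ba[2L]
  dd_w <- -100 * a * ratio^a / p$ba[2L]
  se <- sqrt((dd_m * p$se[1L])^2 + (dd_w * p$se[2L])^2)
  list(rel_bl = rel, se = se)
}

#' Percent bioluminescence reduction of a mutant
#'
#' `100 * (1 - BL_mutant / BL_wildtype)` through the BA curve and the power
#' law; the wild type expresses all three autoinducers.
#'
#' @inheritParams predict_mutant_bl
#' @return list with `reduction` (percent) and `se`.
#' @export
mutant_reduction <- function(curve, model, mutant) {
  p <- predict_mutant_bl(model, curve, mutant)
  list(reduction = 100 - p$rel_bl, se = p$se)
}

#' Fit the bioluminescence model to a mutant panel
#'
#' Constrained least squares on a panel of observed bioluminescence values.
#' With relative observations (wild type = 100, the default) the
#' normalisation `k` is not identifiable and `alpha` is fixed (default 3.0);
#' the three cooperative weights are fitted.  With absolute observations
#' (`relative = FALSE`) `k`, and optionally `alpha`, are fitted too.
#' All parameters are constrained positive and every mutant's Hill number is
#' kept inside the curve's gamma range by a quadratic barrier.
#'
#' @param curve a `ba_curve` (or synthetic equivalent).
#' @param panel data.frame with columns `mutant` and `bl` (relative, wild
#'   type = 100) or `bl_abs` (absolute, with `relative = FALSE`).
#' @param fixed_alpha exponent to hold fixed; `NULL` frees it (requires
#'   absolute data or a rich panel).
#' @param relative whether observations are wild-type-normalised.
#' @param start optional named starting values.
#' @return a fitted [bl_model()]; `$fit` carries residuals, convergence and
#'   the observation count.
#' @export
fit_bl_model <- function(curve, panel, fixed_alpha = 3.0, relative = TRUE,
                         start = NULL) {
  stopifnot(is.data.frame(panel))
  obs_col <- if (relative) "bl" else "bl_abs"
  if (!all(c("mutant", obs_col) %in% names(panel)))
    stop("panel needs columns 'mutant' and '", obs_col, "'", call. = FALSE)
  sets <- lapply(panel$mutant, parse_mutant)
  obs <- as.numeric(panel[[obs_col]])
  n_obs <- length(obs)

  free_alpha <- is.null(fixed_alpha)
  n_par <- 3L + (!relative) + free_alpha
  if (n_obs < n_par)
    stop(sprintf("under-determined fit: %d free parameters but only %d observations",
                 n_par, n_obs), call. = FALSE)

  rng <- range(curve$gamma)
  mid <- mean(rng)
  p0 <- c(hai1 = mid / 3, ai2 = mid / 3, cai1 = mid / 3)
  if (!relative) {
    a0 <- if (free_alpha) 3 else fixed_alpha
    p0 <- c(p0, k = max(obs) / max(predict(curve, rng[2L]))^a0)
  }
  if (free_alpha) p0 <- c(p0, alpha = 3)
  if (!is.null(start)) p0[names(start)] <- unlist(start)

  pred_fun <- function(p) {
    w <- c("HAI-1" = p[["hai1"]], "AI-2" = p[["ai2"]], "CAI-1" = p[["cai1"]])
    a <- if (free_alpha) p[["alpha"]] else fixed_alpha
    gam <- vapply(sets, function(s) sum(w[s]), numeric(1))
    g_all <- c(gam, sum(w))
    pen <- sum(pmax(0, g_all - rng[2L])^2 + pmax(0, rng[1L] - g_all)^2)
    g_cl <- pmin(pmax(g_all, rng[1L]), rng[2L])
    ba <- predict(curve, g_cl)
    pred <- if (relative) 100 * (ba[seq_len(n_obs)] / ba[n_obs + 1L])^a
            else p[["k"]] * ba[seq_len(n_obs)]^a
    list(pred = pred, penalty = pen)
  }
  objective <- function(logp) {
    p <- exp(logp)                      # positivity by log-parameterisation
    out <- pred_fun(p)
    sum((out$pred - obs)^2) + 1e6 * out$penalty
  }
  opt <- stats::optim(log(p0), objective, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  if (opt$convergence == 1)               # polish from the first optimum
    opt <- stats::optim(opt$par, objective, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("bioluminescence fit did not converge (optim code ", opt$convergence,
         "): ", opt$message, call. = FALSE)
  p <- exp(opt$par)
  out <- pred_fun(p)
  if (out$penalty > 1e-8)
    stop("fitted Hill numbers escaped the simulated gamma range; extend the curve",
         call. = FALSE)
  w <- ai_weights(p[["hai1"]], p[["ai2"]], p[["cai1"]])
  model <- bl_model(k = if (relative) 1 else p[["k"]],
                    alpha = if (free_alpha) p[["alpha"]] else fixed_alpha,
                    weights = w,
                    fit = list(residuals = out$pred - obs,
                               fitted = out$pred,
                               residual_norm = sqrt(sum((out$pred - obs)^2)),
                               n_obs = n_obs,
                               convergence = opt$convergence,
                               relative = relative))
  model
}
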