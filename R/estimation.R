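#' Estimation configuration
#'
#' Settings shared by the curve fitter and the particle swarm optimizer.
#' The swarm defaults (50 particles, 500 iterations, inertia decaying
#' linearly from 0.9 to 0.4, acceleration coefficients 1.5/1.5) are
#' conventional global-best PSO choices; every value is recorded in the
#' fit result.
#'
#' @param free_parameters Character vector of symbol names to estimate
#'   (joint estimation only).
#' @param bounds Named list of `c(low, high)` per free symbol; when `NULL`
#'   the optimizer uses `[0.5x, 2x]` of the initial value.
#' @param swarm_size Number of particles.
#' @param max_iterations PSO iterations.
#' @param inertia Length-2 start/end inertia weights (linear decay).
#' @param c1,c2 Cognitive/social acceleration coefficients.
#' @param seed Integer seed for every stochastic element.
#' @param multi_start Number of deterministic least-squares restarts.
#' @param polish Refine the swarm optimum with a derivative-free local
#'   search (Nelder-Mead).
#' @param zeta_pre Perturbation fraction of the pre-run sensitivity scan
#'   that scales the per-parameter velocity clamps.
#' @param vmax_frac Base velocity clamp as a fraction of each bound range.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free_parameters = NULL, bounds = NULL, swarm_size = 50L,
                       max_iterations = 500L, inertia = c(0.9, 0.4),
                       c1 = 1.5, c2 = 1.5, seed = 1L, multi_start = 10L,
                       polish = TRUE, zeta_pre = 0.05, vmax_frac = 0.2) {
  if (!is.null(bounds)) {
    ok <- vapply(bounds, function(b) length(b) == 2 && all(is.finite(b)) && b[1] < b[2],
                 logical(1))
    if (!all(ok)) stop("fit_config: each bound must be finite c(low, high) with low < high")
  }
  structure(list(free_parameters = free_parameters, bounds = bounds,
                 swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, c1 = c1, c2 = c2, seed = as.integer(seed),
                 multi_start = as.integer(multi_start), polish = polish,
                 zeta_pre = zeta_pre, vmax_frac = vmax_frac),
            class = "fit_config")
}

#' Pair a cultivation condition with its measurements
#'
#' @param condition A [cultivation_condition()].
#' @param observed Data frame with `time_h` and one or both of
#'   `dw_g_per_l`, `bcar_frac`.
#' @return An object of class `batch_experiment`.
#' @export
batch_experiment <- function(condition, observed) {
  stopifnot(inherits(condition, "cultivation_condition"))
  require_columns(observed, "time_h", "batch_experiment observations")
  if (!any(c("dw_g_per_l", "bcar_frac") %in% names(observed)))
    stop("batch_experiment: observed needs dw_g_per_l and/or bcar_frac")
  structure(list(condition = condition, observed = observed),
            class = "batch_experiment")
}

#' Average-relative-error objective over batch experiments
#'
#' Simulates every experiment at its observation times and returns the
#' unweighted mean of `|sim - obs| / obs` pooled over all points and both
#' channels (per-channel weights configurable; a zero weight drops a
#' channel). Zero observations are excluded. A state-constraint penalty
#' `lambda * (total excess)` is added when the raw integration under- or
#' overshoots the admissible biomass/carotene ranges beyond numerical noise;
#' a failed simulation yields an `Inf` sentinel so population optimizers can
#' discard the particle.
#'
#' @param p A [parameter_set()].
#' @param experiments List of [batch_experiment()] objects.
#' @param reactor A [reactor_config()].
#' @param weights Named channel weights, e.g. `c(dw_g_per_l = 1, bcar_frac = 1)`.
#' @param lambda State-constraint penalty magnitude.
#' @param rtol,atol Solver tolerances passed to [simulate_batch()].
#' @return Scalar objective >= 0 (or `Inf` on simulation failure).
#' @export
relative_error_objective <- function(p, experiments,
                                     reactor = reactor_config(),
                                     weights = c(dw_g_per_l = 1, bcar_frac = 1),
                                     lambda = 1e3, rtol = 1e-8, atol = 1e-10) {
  devs <- numeric(0)
  wts <- numeric(0)
  penalty <- 0
  for (ex in experiments) {
    stopifnot(inherits(ex, "batch_experiment"))
    traj <- tryCatch(
      suppressWarnings(simulate_batch(ex$condition, p, reactor,
                                      times = ex$observed$time_h,
                                      rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    fl <- attr(traj, "flags")
    excess <- max(0, fl$undershoot_X - 1e-9) + max(0, fl$undershoot_W - 1e-9) +
      max(0, fl$overshoot_W - 1e-9)
    penalty <- penalty + lambda * excess
    for (ch in names(weights)) {
      if (!ch %in% names(ex$observed) || weights[[ch]] == 0) next
      o <- ex$observed[[ch]]
      s <- stats::approx(traj$time_h, traj[[ch]], xout = ex$observed$time_h,
                         rule = 2)$y
      keep <- o != 0
      devs <- c(devs, abs(s[keep] - o[keep]) / o[keep])
      wts <- c(wts, rep(weights[[ch]], sum(keep)))
    }
  }
  if (!length(devs)) stop("relative_error_objective: no usable observations")
  sum(devs * wts) / sum(wts) + penalty
}

# ---- single-factor curve fitting --------------------------------------------

curve_model <- function(kind) {
  switch(kind,
    monod = list(
      par = c("a", "K"),
      fn = function(th, x) th[["a"]] * x / (th[["K"]] + x),
      bounds = function(x, y) list(a = c(1e-8, 10 * max(abs(y)) + 1e-6),
                                   K = c(1e-8, 10 * max(x)))),
    aiba = list(
      par = c("a", "K_s", "K_i"),
      fn = function(th, x) th[["a"]] * x / (x + th[["K_s"]] + x^2 / th[["K_i"]]),
      bounds = function(x, y) list(a = c(1e-8, 10 * max(abs(y)) + 1e-6),
                                   K_s = c(1e-2, 10 * max(x)),
                                   K_i = c(1e-2, 100 * max(x)))),
    arrhenius_diff = list(
      par = c("A", "B", "E_a", "E_b"),
      fn = function(th, x) th[["A"]] * exp(-th[["E_a"]] / (R_GAS * (x + 273.15))) -
                           th[["B"]] * exp(-th[["E_b"]] / (R_GAS * (x + 273.15))),
      bounds = function(x, y) list(A = c(1e-3, 1e3), B = c(1e-3, 1e3),
                                   E_a = c(1e-3, 50), E_b = c(1e-3, 50))),
    carotene_nitrogen = list(
      par = c("a", "K", "b"),
      fn = function(th, x) th[["a"]] * (th[["b"]] + 1 - th[["K"]] / x) * th[["K"]] / x,
      bounds = function(x, y) list(a = c(1e-8, 1e3),
                                   K = c(max(min(x) / 10, 1e-6), max(x)),
                                   b = c(1e-4, 10))),
    stop("unknown curve kind: ", kind))
}

#' Fit a single-factor rate response curve
#'
#' Deterministic bounded least squares (Levenberg-Marquardt) with seeded
#' multi-start over the parameter box, applied to one of the single-factor
#' rate laws: Monod (`a S/(K+S)`), Aiba (`a I/(I + K_s + I^2/K_i)`), the
#' double-Arrhenius temperature difference, or the nitrogen prefactor of the
#' carotene rate law (`a [b + 1 - K/N] K/N`). For the latter the rate scale
#' `a` is not jointly identifiable with `(K, b)` and should be passed in
#' `fixed` (a designed experiment knows it from the held factor levels).
#'
#' A flat response triggers a non-identifiability warning, as does a
#' parameter-correlation diagnostic exceeding 0.999 at the optimum (the
#' diagnostic names the widest-confidence parameter).
#'
#' @param kind `"monod"`, `"aiba"`, `"arrhenius_diff"` or
#'   `"carotene_nitrogen"`.
#' @param data An `experiment_table` or data frame with `factor_value` and
#'   `rate` columns.
#' @param cfg A [fit_config()] (uses `multi_start`, `seed`, `bounds`).
#' @param fixed Named numeric of parameters to hold fixed.
#' @return A `fit_result`: `parameters` (named vector), `objective`
#'   (residual sum of squares), `trace` (best objective per start),
#'   `converged`, `seed`.
#' @export
fit_single_factor_curve <- function(kind, data, cfg = fit_config(),
                                    fixed = NULL) {
  require_columns(data, c("factor_value", "rate"), "experiment table")
  x <- data$factor_value
  y <- data$rate
  m <- curve_model(kind)
  free <- setdiff(m$par, names(fixed))
  if (length(x) < length(free))
    stop("fit_single_factor_curve: fewer points than free parameters")
  if (stats::sd(y) == 0) {
    warning("fit_single_factor_curve: flat response; parameters are not ",
            "identifiable (widest-CI parameter: ", free[length(free)], ")")
    th <- stats::setNames(rep(NA_real_, length(m$par)), m$par)
    th[names(fixed)] <- fixed
    return(structure(list(parameters = th, objective = 0, trace = numeric(0),
                          converged = FALSE, seed = cfg$seed),
                     class = "fit_result"))
  }
  bounds <- m$bounds(x, y)
  if (!is.null(cfg$bounds)) bounds[names(cfg$bounds)] <- cfg$bounds
  lo <- vapply(bounds[free], `[`, numeric(1), 1)
  hi <- vapply(bounds[free], `[`, numeric(1), 2)

  resid_fn <- function(th_free) {
    th <- c(stats::setNames(th_free, free), fixed)
    m$fn(th, x) - y
  }
  # log-uniform starts: the half-velocity and scale constants span orders of
  # magnitude, so uniform sampling would almost never start near a small K
  starts <- withr::with_seed(cfg$seed, {
    s <- matrix(stats::runif(cfg$multi_start * length(free)),
                nrow = cfg$multi_start)
    exp(sweep(sweep(s, 2, log(hi) - log(lo), "*"), 2, log(lo), "+"))
  })
  best <- NULL
  trace <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, par = stats::setNames(fit$par, free), fit = fit)
    trace <- c(trace, if (is.null(best)) NA_real_ else best$sse)
  }
  if (is.null(best))
    stop("fit_single_factor_curve: all starts failed")
  check_identifiability(best$fit, free)
  th <- stats::setNames(rep(NA_real_, length(m$par)), m$par)
  th[free] <- best$par
  th[names(fixed)] <- fixed
  structure(list(parameters = th, objective = best$sse, trace = cummin(trace),
                 converged = best$fit$info %in% 1:4, seed = cfg$seed),
            class = "fit_result")
}

# correlation diagnostic from the LM Jacobian; warns when a pair is
# numerically collinear at the optimum
check_identifiability <- function(fit, free, limit = 0.999) {
  J <- fit$jac
  if (is.null(J) || length(free) < 2) return(invisible(NULL))
  JTJ <- crossprod(J)
  cv <- tryCatch(solve(JTJ), error = function(e) NULL)
  if (is.null(cv)) {
    warning("fit_single_factor_curve: singular Jacobian; parameters not ",
            "jointly identifiable")
    return(invisible(NULL))
  }
  se <- sqrt(pmax(diag(cv), 0))
  cor_m <- cv / tcrossprod(se)
  diag(cor_m) <- 0
  if (any(abs(cor_m) > limit, na.rm = TRUE)) {
    widest <- free[which.max(se)]
    warning("fit_single_factor_curve: near-collinear parameters at the ",
            "optimum; widest-CI parameter: ", widest)
  }
  invisible(NULL)
}

#' Fit the growth-decay ODE to a biomass time course
#'
#' Under constant conditions the growth-decay ODE has the logistic closed
#' form `X(t) = Xs / (1 + (Xs/X0 - 1) exp(-mu0 t))` with carrying capacity
#' `Xs = mu0 / mu_d`. Fits `(mu0, mu_d)` by bounded Levenberg-Marquardt with
#' the initial biomass fixed at the first observation.
#'
#' @param times Sampling times, h.
#' @param X Biomass dry weights, g/L.
#' @param cfg A [fit_config()].
#' @return A `fit_result` with parameters `mu0`, `mu_d`.
#' @export
fit_growth_curve <- function(times, X, cfg = fit_config()) {
  stopifnot(length(times) == length(X), length(X) >= 3, all(X > 0))
  X0 <- X[1]
  model <- function(th, t) {
    Xs <- th[["mu0"]] / th[["mu_d"]]
    Xs / (1 + (Xs / X0 - 1) * exp(-th[["mu0"]] * t))
  }
  fit_timecourse(times, X, model, par = c("mu0", "mu_d"),
                 lo = c(1e-6, 1e-4), hi = c(5, 100), cfg = cfg)
}

#' Fit the logistic carotene ceiling to a content time course
#'
#' Under a constant positive environmental prefactor `r`, the content obeys
#' `dW/dt = r (1 - W/w_max)` with solution
#' `W(t) = w_max + (W0 - w_max) exp(-r t / w_max)`. Fits `(r, w_max)` with
#' the initial content fixed at the first observation.
#'
#' @param times Sampling times, h.
#' @param W Carotene content, fraction of DW.
#' @param cfg A [fit_config()].
#' @return A `fit_result` with parameters `r`, `w_max`.
#' @export
fit_content_curve <- function(times, W, cfg = fit_config()) {
  stopifnot(length(times) == length(W), length(W) >= 3)
  W0 <- W[1]
  model <- function(th, t)
    th[["w_max"]] + (W0 - th[["w_max"]]) * exp(-th[["r"]] * t / th[["w_max"]])
  fit_timecourse(times, W, model, par = c("r", "w_max"),
                 lo = c(1e-10, 1e-5), hi = c(1, 1), cfg = cfg)
}

fit_timecourse <- function(times, y, model, par, lo, hi, cfg) {
  resid_fn <- function(th) model(stats::setNames(th, par), times) - y
  starts <- withr::with_seed(cfg$seed, {
    s <- matrix(stats::runif(cfg$multi_start * length(par)), ncol = length(par))
    exp(sweep(sweep(s, 2, log(hi) - log(lo), "*"), 2, log(lo), "+"))
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, par = stats::setNames(fit$par, par), fit = fit)
  }
  if (is.null(best)) stop("time-course fit: all starts failed")
  structure(list(parameters = best$par, objective = best$sse,
                 trace = best$sse, converged = best$fit$info %in% 1:4,
                 seed = cfg$seed),
            class = "fit_result")
}

# ---- particle swarm optimization --------------------------------------------

#' Adaptive particle swarm parameter estimation
#'
#' Global-best PSO with linearly decaying inertia and per-parameter velocity
#' clamps scaled by a pre-run sensitivity scan: before the swarm starts, each
#' free parameter is perturbed by `+/- zeta_pre` around the initial point and
#' the objective change is measured; more sensitive parameters receive
#' proportionally tighter velocity limits. One particle is seeded at the
#' initial point, so the final objective can never exceed the initial one.
#' Fixed seeds give bit-identical results. Optionally the swarm optimum is
#' polished with a derivative-free Nelder-Mead local search.
#'
#' Two calling modes: with `experiments`, the objective is
#' [relative_error_objective()] over the free symbols of a
#' [parameter_set()] `initial`; with an explicit `objective` function, any
#' named numeric `initial` is optimized directly.
#'
#' @param experiments List of [batch_experiment()] (ignored when `objective`
#'   is given).
#' @param cfg A [fit_config()]; `free_parameters` selects the symbols to
#'   estimate in parameter-set mode.
#' @param initial A [parameter_set()] (parameter-set mode) or named numeric
#'   vector (explicit-objective mode). Must lie inside the bounds.
#' @param objective Optional function of a named numeric vector.
#' @param reactor,weights,lambda Passed to [relative_error_objective()].
#' @return A `fit_result`: `parameters` (a [parameter_set()] in
#'   parameter-set mode, else a named vector), `objective`, non-increasing
#'   `trace` of the best objective per iteration, `converged`, `seed`.
#' @export
pso_optimize <- function(experiments = NULL, cfg = fit_config(), initial,
                         objective = NULL, reactor = reactor_config(),
                         weights = c(dw_g_per_l = 1, bcar_frac = 1),
                         lambda = 1e3) {
  set_mode <- inherits(initial, "parameter_set")
  if (set_mode) {
    free <- cfg$free_parameters
    if (is.null(free)) free <- names(flatten_parameters(initial))
    flat0 <- flatten_parameters(initial)
    x0 <- flat0[free]
    if (is.null(objective)) {
      if (is.null(experiments))
        stop("pso_optimize: need experiments or an explicit objective")
      objective <- function(theta) {
        pth <- tryCatch(update_parameters(initial, stats::setNames(theta, free)),
                        error = function(e) NULL)
        if (is.null(pth)) return(Inf)
        relative_error_objective(pth, experiments, reactor, weights, lambda)
      }
    }
  } else {
    x0 <- initial
    free <- names(x0)
    if (is.null(objective)) stop("pso_optimize: vector mode needs an objective")
  }
  if (is.null(free) || any(!nzchar(free)))
    stop("pso_optimize: free parameters must be named")

  if (!is.null(cfg$bounds)) {
    lo <- vapply(cfg$bounds[free], `[`, numeric(1), 1)
    hi <- vapply(cfg$bounds[free], `[`, numeric(1), 2)
  } else {
    lo <- 0.5 * x0; hi <- 2 * x0
  }
  if (any(x0 < lo - 1e-12) || any(x0 > hi + 1e-12))
    stop("pso_optimize: initial point lies outside the bounds for: ",
         paste(free[x0 < lo | x0 > hi], collapse = ", "))
  d <- length(free)
  rng <- hi - lo

  f0 <- objective(x0)
  # pre-run sensitivity: tighter clamps for more sensitive parameters
  sens <- vapply(seq_len(d), function(j) {
    up <- x0; up[j] <- min(hi[j], x0[j] * (1 + cfg$zeta_pre))
    dn <- x0; dn[j] <- max(lo[j], x0[j] * (1 - cfg$zeta_pre))
    fu <- objective(up); fd <- objective(dn)
    if (!is.finite(fu)) fu <- f0
    if (!is.finite(fd)) fd <- f0
    max(abs(fu - f0), abs(fd - f0))
  }, numeric(1))
  ref <- stats::median(sens[sens > 0])
  scale <- if (is.finite(ref) && ref > 0) pmin(2, pmax(0.25, ref / (sens + ref)))
           else rep(1, d)
  vmax <- cfg$vmax_frac * rng * scale

  res <- withr::with_seed(cfg$seed, {
    n <- cfg$swarm_size
    pos <- matrix(stats::runif(n * d), n, d, dimnames = list(NULL, free))
    pos <- sweep(sweep(pos, 2, rng, "*"), 2, lo, "+")
    pos[1, ] <- x0
    vel <- matrix(0, n, d)
    fvals <- apply(pos, 1, objective)
    if (all(!is.finite(fvals)))
      stop("pso_optimize: entire initial swarm is infeasible (objective is ",
           "Inf everywhere); check bounds and state constraints")
    pbest <- pos; pbest_f <- fvals
    gi <- which.min(pbest_f)
    gbest <- pbest[gi, ]; gbest_f <- pbest_f[gi]
    trace <- numeric(cfg$max_iterations)
    for (it in seq_len(cfg$max_iterations)) {
      wgt <- cfg$inertia[1] + (cfg$inertia[2] - cfg$inertia[1]) *
        (it - 1) / max(1, cfg$max_iterations - 1)
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      vel <- wgt * vel + cfg$c1 * r1 * (pbest - pos) +
        cfg$c2 * r2 * sweep(-pos, 2, gbest, "+")
      vel <- pmin(pmax(vel, matrix(-vmax, n, d, byrow = TRUE)),
                  matrix(vmax, n, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lo, n, d, byrow = TRUE)),
                  matrix(hi, n, d, byrow = TRUE))
      fvals <- apply(pos, 1, objective)
      imp <- fvals < pbest_f
      pbest[imp, ] <- pos[imp, , drop = FALSE]
      pbest_f[imp] <- fvals[imp]
      gi <- which.min(pbest_f)
      if (pbest_f[gi] < gbest_f) { gbest <- pbest[gi, ]; gbest_f <- pbest_f[gi] }
      trace[it] <- gbest_f
    }
    if (cfg$polish) {
      pol <- stats::optim(gbest, function(th) {
        th <- pmin(pmax(th, lo), hi)
        objective(th)
      }, method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-12))
      if (pol$value < gbest_f) {
        gbest <- pmin(pmax(pol$par, lo), hi)
        gbest_f <- pol$value
      }
    }
    list(par = stats::setNames(gbest, free), value = gbest_f, trace = trace)
  })

  params <- if (set_mode) update_parameters(initial, res$par) else res$par
  structure(list(parameters = params, estimates = res$par,
                 objective = res$value, trace = res$trace,
                 converged = TRUE, seed = cfg$seed),
            class = "fit_result")
}

# ---- perturbation sensitivity analysis --------------------------------------

#' Random-perturbation sensitivity scan of the objective
#'
#' For each parameter independently: draw `Q` perturbation fractions
#' uniformly in `[-zeta, +zeta]` (seeded), multiply that single parameter,
#' re-evaluate (not re-optimize) the objective with all other parameters
#' fixed, and summarize the objective per perturbation bin by quartiles for
#' box plots. A parameter is flagged `min_at_zero` when no perturbed
#' evaluation beats the unperturbed objective (up to a 1e-8 numerical
#' floor).
#'
#' @param p A [parameter_set()]: the point being scanned.
#' @param experiments List of [batch_experiment()].
#' @param Q Draws per parameter.
#' @param zeta Perturbation half-range as a fraction (0 allowed: all draws
#'   collapse to the unperturbed point).
#' @param seed Integer seed.
#' @param parameters Symbols to scan; default all 20.
#' @param bins Number of perturbation bins for the quartile summary.
#' @param reactor,weights,lambda Passed to [relative_error_objective()].
#' @return A `sensitivity_report`: `draws` (long data frame `parameter`,
#'   `perturbation_frac`, `objective`), `baseline`, `quartiles`,
#'   `min_at_zero` (named logical), and the scan settings.
#' @export
sensitivity_scan <- function(p, experiments, Q = 100L, zeta = 0.05,
                             seed = 1L, parameters = NULL, bins = 5L,
                             reactor = reactor_config(),
                             weights = c(dw_g_per_l = 1, bcar_frac = 1),
                             lambda = 1e3) {
  stopifnot(Q >= 1, zeta >= 0, zeta < 1)
  flat <- flatten_parameters(p)
  if (is.null(parameters)) parameters <- names(flat)
  stopifnot(all(parameters %in% names(flat)))
  obj <- function(pp) relative_error_objective(pp, experiments, reactor,
                                               weights, lambda)
  baseline <- obj(p)
  draws <- withr::with_seed(seed, {
    out <- vector("list", length(parameters))
    for (k in seq_along(parameters)) {
      nm <- parameters[k]
      fr <- stats::runif(Q, -zeta, zeta)
      ov <- vapply(fr, function(f) {
        pp <- tryCatch(update_parameters(p, stats::setNames(flat[nm] * (1 + f), nm)),
                       error = function(e) NULL)
        if (is.null(pp)) return(Inf)
        obj(pp)
      }, numeric(1))
      out[[k]] <- data.frame(parameter = nm, perturbation_frac = fr,
                             objective = ov)
    }
    do.call(rbind, out)
  })
  rownames(draws) <- NULL

  edges <- seq(-zeta, zeta, length.out = bins + 1L)
  qs <- NULL
  for (nm in parameters) {
    dsub <- draws[draws$parameter == nm, ]
    bin <- if (zeta > 0) cut(dsub$perturbation_frac, edges, include.lowest = TRUE)
           else factor(rep("[0,0]", nrow(dsub)))
    for (lv in levels(bin)) {
      v <- dsub$objective[bin == lv]
      if (!length(v)) next
      qq <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      qs <- rbind(qs, data.frame(parameter = nm, bin = lv, min = qq[1],
                                 q1 = qq[2], median = qq[3], q3 = qq[4],
                                 max = qq[5]))
    }
  }
  min_at_zero <- vapply(parameters, function(nm)
    baseline <= min(draws$objective[draws$parameter == nm]) + 1e-8, logical(1))
  structure(list(draws = draws, baseline = baseline, quartiles = qs,
                 min_at_zero = min_at_zero, Q = as.integer(Q), zeta = zeta,
                 seed = as.integer(seed)),
            class = "sensitivity_report")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", format(x$objective, digits = 6),
      if (isTRUE(x$converged)) "(converged)" else "(not converged)", "\n")
  if (inherits(x$parameters, "parameter_set")) print(x$parameters)
  else print(x$parameters)
  invisible(x)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> Q =", x$Q, " zeta =", x$zeta,
      " baseline =", format(x$baseline, digits = 6), "\n")
  cat("  min at zero perturbation:", sum(x$min_at_zero), "/",
      length(x$min_at_zero), "parameters\n")
  invisible(x)
}
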