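# Independent oracles used across tests.

# Fixed-step classic RK4 integration of the coupled biomass/carotene system,
# built from the exported rate primitives (not the package solver). Same
# state-clipping rule as the simulator: states are projected onto their
# admissible ranges before rate evaluation, and a rate pushing a pinned state
# further out is zeroed.
rk4_batch <- function(cond, p, reactor, dt = 0.01, out_times = NULL) {
  if (is.null(out_times)) out_times <- seq(0, cond$duration, by = 1)
  w_max <- p$carotene$w_max
  deriv <- function(t, X, W) {
    Xc <- max(X, 0)
    Wc <- min(max(W, 0), w_max)
    I0 <- irradiance_at_time(min(t, cond$duration - 1e-12),
                             cond$photoperiod, cond$light)
    Iav <- average_light_intensity(I0, Xc, reactor)
    env <- culture_env(cond$temperature, Iav, cond$nitrogen, cond$carbon)
    mu0 <- specific_growth_rate(env, p)
    dX <- biomass_rate(Xc, mu0, p$growth$mu_d)
    dW <- carotene_rate(culture_state(Xc, Wc), env, p)
    if (X <= 0 && dX < 0) dX <- 0
    if (W <= 0 && dW < 0) dW <- 0
    if (W >= w_max && dW > 0) dW <- 0
    c(dX, dW)
  }
  # step edges: uniform dt, plus photoperiod transitions and output times
  breaks <- carokin:::photoperiod_breaks(cond$photoperiod, cond$duration)
  grid <- sort(unique(c(seq(0, cond$duration, by = dt), breaks, out_times,
                        cond$duration)))
  X <- cond$initial_DW; W <- cond$initial_W
  out <- matrix(NA_real_, length(out_times), 2)
  oi <- match(round(out_times, 10), round(grid, 10))
  stopifnot(!anyNA(oi))
  res_X <- numeric(length(grid)); res_W <- numeric(length(grid))
  res_X[1] <- X; res_W[1] <- W
  for (i in seq_len(length(grid) - 1)) {
    t0 <- grid[i]; h <- grid[i + 1] - grid[i]
    k1 <- deriv(t0, X, W)
    k2 <- deriv(t0 + h / 2, X + h / 2 * k1[1], W + h / 2 * k1[2])
    k3 <- deriv(t0 + h / 2, X + h / 2 * k2[1], W + h / 2 * k2[2])
    k4 <- deriv(t0 + h, X + h * k3[1], W + h * k3[2])
    X <- X + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    W <- W + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    res_X[i + 1] <- X; res_W[i + 1] <- W
  }
  data.frame(time_h = out_times,
             dw_g_per_l = pmax(res_X[oi], 0),
             bcar_frac = pmin(pmax(res_W[oi], 0), w_max))
}

# relative difference with a floor: points where both values are essentially
# zero (|.| < atol) count as agreeing
rel_diff <- function(a, b, atol = 1e-10) {
  d <- abs(a - b) / pmax(abs(a), abs(b))
  d[pmax(abs(a), abs(b)) < atol] <- 0
  d
}

expect_close <- function(actual, expected, rel = 0.02) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
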