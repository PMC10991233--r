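#' Batch cultivation condition
#'
#' One row of the validation-experiment design: initial biomass, photoperiod,
#' temperature, incident light, carbon, nitrate and duration. Nitrate and
#' carbon are held constant over the run (no uptake ODEs are part of the
#' model; carbon is replenished by pH-stat CO2 dosing and nitrate stays in
#' excess in the experiments the model describes).
#'
#' @param initial_DW Initial biomass dry weight, g/L.
#' @param photoperiod Light/dark hours per 24 h cycle, e.g. `c(14, 10)`.
#' @param temperature Culture temperature, degrees C.
#' @param light Incident photon flux density during the light phase,
#'   umol photons m-2 s-1.
#' @param carbon Inorganic carbon, mM.
#' @param nitrogen Nitrate, mg/L.
#' @param duration Batch length, h.
#' @param initial_W Initial carotene content, fraction of DW.
#' @param label Free-text label.
#' @return An object of class `cultivation_condition`.
#' @export
cultivation_condition <- function(initial_DW = 0.1, photoperiod = c(24, 0),
                                  temperature = 25, light = 600, carbon = 5,
                                  nitrogen = 500, duration = 144,
                                  initial_W = 0.01, label = "") {
  check_photoperiod(photoperiod)
  vals <- c(initial_DW = initial_DW, temperature = temperature, light = light,
            carbon = carbon, nitrogen = nitrogen, duration = duration,
            initial_W = initial_W)
  if (any(!is.finite(vals)) || any(vals[c("initial_DW", "carbon", "nitrogen",
                                          "duration")] <= 0))
    stop("cultivation_condition: initial_DW, carbon, nitrogen and duration must be positive")
  if (initial_W < 0) stop("cultivation_condition: initial_W must be >= 0")
  structure(list(initial_DW = initial_DW, photoperiod = photoperiod,
                 temperature = temperature, light = light, carbon = carbon,
                 nitrogen = nitrogen, duration = duration,
                 initial_W = initial_W, label = label),
            class = "cultivation_condition")
}

# Per-segment constants of the coupled ODE right-hand side. Everything not
# depending on (X, W) is evaluated once per light/dark segment.
segment_context <- function(cond, p, reactor, light_on) {
  g <- p$growth; w <- p$carotene
  T_K <- cond$temperature + 273.15
  I0 <- if (light_on) cond$light else 0
  list(
    I0 = I0,
    attenuate = reactor$mode == "beer_lambert" && I0 > 0,
    kaL = reactor$k_a * reactor$light_path,
    mu_pref = g$mu_max *
      temperature_factor(T_K, g$A, g$B, g$E_a, g$E_b, p$R) *
      substrate_factor(cond$carbon, g$K_C) *
      substrate_factor(cond$nitrogen, g$K_N),
    K_s = g$K_s, K_i = g$K_i, mu_d = g$mu_d,
    w_pref = (w$b + (1 - w$K_NW / cond$nitrogen)) * (w$K_NW / cond$nitrogen) *
      (1 - w$K_CW / cond$carbon) * (w$K_CW / cond$carbon) *
      temperature_factor(T_K, w$A_w, w$B_w, w$E_aw, w$E_bw, p$R),
    K_sw = w$K_sw, K_iw = w$K_iw, w_max = w$w_max
  )
}

# Right-hand side shared by the adaptive solver; flags clipping events in the
# counter environment `tally`. States are evaluated at their admissible
# projections so small solver under/overshoots cannot inject NaNs.
segment_rhs <- function(t, y, ctx, tally = NULL) {
  X <- max(y[[1]], 0)
  W <- min(max(y[[2]], 0), ctx$w_max)
  if (ctx$I0 > 0) {
    Iav <- if (ctx$attenuate) {
      tau <- ctx$kaL * X
      if (tau < 1e-12) ctx$I0 else ctx$I0 * (1 - exp(-tau)) / tau
    } else ctx$I0
    lf_g <- Iav / (Iav + ctx$K_s + Iav^2 / ctx$K_i)
    lf_w <- Iav / (Iav + ctx$K_sw + Iav^2 / ctx$K_iw)
  } else {
    lf_g <- 0; lf_w <- 0
  }
  dX <- ctx$mu_pref * lf_g * X - ctx$mu_d * X^2
  dW <- ctx$w_pref * lf_w * (1 - W / ctx$w_max)
  clip <- FALSE
  if (y[[1]] <= 0 && dX < 0) { dX <- 0; clip <- TRUE }
  if (y[[2]] <= 0 && dW < 0) { dW <- 0; clip <- TRUE }
  if (y[[2]] >= ctx$w_max && dW > 0) { dW <- 0; clip <- TRUE }
  if (!is.null(tally)) {
    tally$total <- tally$total + 1L
    if (clip) tally$clipped <- tally$clipped + 1L
    if (y[[2]] < tally$minW) tally$minW <- y[[2]]
    if (y[[2]] > tally$maxW) tally$maxW <- y[[2]]
    if (y[[1]] < tally$minX) tally$minX <- y[[1]]
  }
  list(c(dX, dW))
}

# light/dark transition times within [0, duration]
photoperiod_breaks <- function(photoperiod, duration) {
  lt <- photoperiod[1]
  if (lt <= 0 || lt >= 24) return(numeric(0))
  days <- ceiling(duration / 24)
  br <- sort(c(24 * (0:days) + lt, 24 * (1:days)))
  br[br > 0 & br < duration]
}

#' Simulate a batch culture
#'
#' Integrates the coupled biomass/carotene ODE system with `lsoda`, holding
#' nitrate and carbon constant at the condition values and restarting the
#' integrator at every light/dark transition. States are clipped to their
#' physical ranges (X >= 0, 0 <= W <= w_max) with the events flagged; runs
#' with more than 1 % flagged right-hand-side evaluations raise a prominent
#' warning.
#'
#' @param cond A [cultivation_condition()].
#' @param p A [parameter_set()].
#' @param reactor A [reactor_config()].
#' @param times Output grid, h (within [0, duration]); default hourly.
#' @param rtol,atol Solver tolerances.
#' @return A `trajectory` data frame with columns `time_h`, `dw_g_per_l`,
#'   `bcar_frac`, `bcar_pct`, `i_av`, and attributes `flags` (clipping
#'   tally), `condition`, `parameters`.
#' @export
simulate_batch <- function(cond, p, reactor = reactor_config(), times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cond, "cultivation_condition"),
            inherits(p, "parameter_set"), inherits(reactor, "reactor_config"))
  if (is.null(times)) times <- seq(0, cond$duration, by = 1)
  times <- sort(unique(times))
  if (min(times) < 0 || max(times) > cond$duration + 1e-9)
    stop("simulate_batch: output times must lie within [0, duration]")
  if (times[1] > 0) times <- c(0, times)

  breaks <- photoperiod_breaks(cond$photoperiod, cond$duration)
  edges <- sort(unique(c(0, breaks, cond$duration)))
  tally <- new.env(parent = emptyenv())
  tally$total <- 0L; tally$clipped <- 0L
  tally$minW <- Inf; tally$maxW <- -Inf; tally$minX <- Inf

  y <- c(X = cond$initial_DW, W = cond$initial_W)
  out_t <- numeric(0); out_y <- NULL
  for (k in seq_len(length(edges) - 1L)) {
    t0 <- edges[k]; t1 <- edges[k + 1L]
    light_on <- (t0 %% 24) < cond$photoperiod[1] - 1e-9 ||
      cond$photoperiod[1] >= 24
    ctx <- segment_context(cond, p, reactor, light_on)
    seg_times <- sort(unique(c(t0, times[times > t0 + 1e-12 & times <= t1 + 1e-12], t1)))
    sol <- deSolve::lsoda(y, seg_times,
                          function(t, y, parms) segment_rhs(t, y, parms, tally),
                          parms = ctx, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("simulate_batch: solver failed in segment [", t0, ", ", t1,
           "] h; last good state X=", y[1], " W=", y[2])
    y <- c(X = unname(sol[nrow(sol), "X"]), W = unname(sol[nrow(sol), "W"]))
    keep <- sol[, "time"] %in% times & (sol[, "time"] < t1 - 1e-12 | k == length(edges) - 1L)
    out_t <- c(out_t, sol[keep, "time"])
    out_y <- rbind(out_y, sol[keep, c("X", "W"), drop = FALSE])
  }

  X <- pmax(out_y[, "X"], 0)
  W <- pmin(pmax(out_y[, "W"], 0), p$carotene$w_max)
  I0_t <- irradiance_at_time(pmin(out_t, cond$duration - 1e-12),
                             cond$photoperiod, cond$light)
  Iav <- average_light_intensity(I0_t, X, reactor)
  flags <- list(clipped = tally$clipped, total = tally$total,
                clipped_fraction = if (tally$total) tally$clipped / tally$total else 0,
                undershoot_X = max(0, -tally$minX),
                undershoot_W = max(0, -tally$minW),
                overshoot_W = max(0, tally$maxW - p$carotene$w_max))
  if (flags$clipped_fraction > 0.01)
    warning(sprintf(paste0("simulate_batch: %.1f%% of right-hand-side evaluations ",
                           "were clipped to keep X and W in range (condition '%s'); ",
                           "the rate law is driving the state out of bounds"),
                    100 * flags$clipped_fraction, cond$label), call. = FALSE)
  traj <- data.frame(time_h = out_t, dw_g_per_l = X, bcar_frac = W,
                     bcar_pct = 100 * W, i_av = Iav)
  rownames(traj) <- NULL
  structure(traj, flags = flags, condition = cond, parameters = p,
            class = c("trajectory", "data.frame"))
}

#' Biomass carrying capacity of the growth-decay ODE
#'
#' Non-trivial root of `mu_0 X - mu_d X^2`.
#'
#' @param mu0 Specific growth rate, 1/h (>= 0).
#' @param mu_d Decay coefficient (> 0).
#' @return `mu0 / mu_d`, g/L.
#' @export
steady_state_biomass <- function(mu0, mu_d) {
  if (mu_d <= 0) stop("steady_state_biomass: mu_d must be > 0")
  mu0 / mu_d
}

#' Percent deviation between simulated and observed trajectories
#'
#' Matches observations to the simulation by linear interpolation in time and
#' returns `100 |sim - obs| / obs` per point and channel. Zero observations
#' are excluded with a warning.
#'
#' @param sim A `trajectory` from [simulate_batch()].
#' @param obs Data frame with `time_h` and one or both of `dw_g_per_l`,
#'   `bcar_frac`.
#' @return Data frame `time_h`, `channel`, `deviation_pct`.
#' @export
relative_deviation <- function(sim, obs) {
  stopifnot(is.data.frame(obs), "time_h" %in% names(obs))
  channels <- intersect(c("dw_g_per_l", "bcar_frac"), names(obs))
  if (!length(channels))
    stop("relative_deviation: obs has neither dw_g_per_l nor bcar_frac")
  out <- NULL
  for (ch in channels) {
    o <- obs[[ch]]
    s <- stats::approx(sim$time_h, sim[[ch]], xout = obs$time_h, rule = 2)$y
    zero <- o == 0
    if (any(zero))
      warning("relative_deviation: excluded ", sum(zero),
              " zero observation(s) in channel ", ch)
    out <- rbind(out, data.frame(time_h = obs$time_h[!zero], channel = ch,
                                 deviation_pct = 100 * abs(s[!zero] - o[!zero]) / o[!zero]))
  }
  rownames(out) <- NULL
  out
}
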