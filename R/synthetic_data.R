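#' Multiplicative measurement noise model
#'
#' Lognormal multiplicative noise: each value is multiplied by
#' `exp(rnorm(0, sigma))` with `sigma = sqrt(log(1 + cv^2))`, so the noise is
#' median-preserving (mean-zero in log space) and sign-preserving.
#' Measurement channels (dry weight, content) are additionally floored at a
#' small positive minimum, mirroring the detection limit of gravimetric and
#' photometric assays; derived specific rates are never floored, since parts
#' of the carotene response are legitimately negative.
#'
#' @param cv Coefficient of variation (>= 0); 0 disables noise.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param floor Minimum reportable value.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, seed = 1L, floor = 1e-9) {
  if (cv < 0) stop("noise_model: cv must be >= 0")
  structure(list(cv = cv, seed = as.integer(seed), floor = floor),
            class = "noise_model")
}

# draws are consumed from a seeded local RNG stream; the caller's RNG state
# is untouched. Multiplicative noise preserves sign (specific rates can be
# legitimately negative); the detection-limit floor is applied only to
# measurement channels (`floor_at = TRUE`), never to derived rates.
apply_noise <- function(x, noise, floor_at = FALSE) {
  y <- if (noise$cv == 0) x else {
    sigma <- sqrt(log(1 + noise$cv^2))
    withr::with_seed(noise$seed,
                     x * exp(stats::rnorm(length(x), 0, sigma)))
  }
  if (floor_at) y <- pmax(y, noise$floor)
  y
}

default_grid <- function(factor) {
  switch(factor,
         temperature = seq(10, 40, length.out = 24),
         light = seq(0, 2000, length.out = 24),
         nitrogen = seq(0, 500, length.out = 24),
         carbon = seq(0, 500, length.out = 24))
}

default_held <- function(channel) {
  if (channel == "growth") culture_env(temperature = 28, I_av = 600,
                                       nitrogen = 500, carbon = 50)
  else culture_env(temperature = 10, I_av = 600, nitrogen = 500, carbon = 200)
}

#' Generate a single-factor rate dataset
#'
#' Emulates the single-factor experiments behind the rate-response curves:
#' one environmental factor is varied over a grid while the others are held
#' fixed, and the specific growth rate (growth channel) or the carotene
#' accumulation rate at W = 0 (carotene channel) is evaluated and optionally
#' corrupted with multiplicative noise.
#'
#' With `hold_at_unity = TRUE` every non-varied factor (including the
#' temperature factor) is replaced by exactly 1, so the response is the pure
#' varied-factor term scaled by `mu_max` (growth) or 1 (carotene) — the
#' idealized design in which the rate-scale parameter is itself
#' recoverable.
#'
#' @param factor One of `"temperature"`, `"light"`, `"nitrogen"`, `"carbon"`
#'   (aliases `"T"`, `"I"`, `"N"`, `"C"` accepted).
#' @param channel `"growth"` or `"carotene"`.
#' @param p A [parameter_set()]; recorded as the truth in the result.
#' @param grid Factor values; defaults to the experimental ranges
#'   (temperature 10-40 C, light 0-2000, nitrate 0-500 mg/L, carbon
#'   0-500 mM), 24 points.
#' @param held A [culture_env()] giving the non-varied factor levels;
#'   defaults to saturating/near-optimal levels per channel.
#' @param noise A [noise_model()]; default noise-free.
#' @param hold_at_unity Replace non-varied factors by exactly 1.
#' @return An `experiment_table` data frame with columns `factor_value`,
#'   `rate` and attributes `factor`, `channel`, `held`, `truth`, `noise`.
#' @export
generate_single_factor_dataset <- function(factor, channel = c("growth", "carotene"),
                                           p = carokin_preset("table1_prior"),
                                           grid = NULL, held = NULL,
                                           noise = noise_model(cv = 0),
                                           hold_at_unity = FALSE) {
  aliases <- c(T = "temperature", I = "light", N = "nitrogen", C = "carbon")
  if (factor %in% names(aliases)) factor <- aliases[[factor]]
  factor <- match.arg(factor, unname(aliases))
  channel <- match.arg(channel)
  stopifnot(inherits(p, "parameter_set"), inherits(noise, "noise_model"))
  if (is.null(grid)) grid <- default_grid(factor)
  if (is.null(held)) held <- default_held(channel)
  if (factor == "temperature" && (min(grid) < -20 || max(grid) > 60))
    stop("generate_single_factor_dataset: temperature grid outside [-20, 60] C guard band")
  if (factor != "temperature" && min(grid) < 0)
    stop("generate_single_factor_dataset: ", factor, " grid must be >= 0")
  if (factor %in% c("nitrogen", "carbon") && channel == "carotene" && min(grid) <= 0)
    stop("generate_single_factor_dataset: carotene channel needs strictly positive ",
         factor, " (it divides the rate law)")

  rate <- if (hold_at_unity) unity_rate(factor, channel, p, grid)
          else full_rate(factor, channel, p, grid, held)
  out <- data.frame(factor_value = grid, rate = apply_noise(rate, noise))
  structure(out, factor = factor, channel = channel, held = held,
            truth = p, noise = noise,
            class = c("experiment_table", "data.frame"))
}

# varied factor alone (times mu_max for the growth channel)
unity_rate <- function(factor, channel, p, grid) {
  g <- p$growth; w <- p$carotene
  if (channel == "growth") {
    g$mu_max * switch(factor,
      light = light_factor(grid, g$K_s, g$K_i),
      nitrogen = substrate_factor(grid, g$K_N),
      carbon = substrate_factor(grid, g$K_C),
      temperature = temperature_factor(grid + 273.15, g$A, g$B, g$E_a, g$E_b, p$R))
  } else {
    switch(factor,
      light = light_factor(grid, w$K_sw, w$K_iw),
      nitrogen = (w$b + (1 - w$K_NW / grid)) * (w$K_NW / grid),
      carbon = (1 - w$K_CW / grid) * (w$K_CW / grid),
      temperature = temperature_factor(grid + 273.15, w$A_w, w$B_w, w$E_aw, w$E_bw, p$R))
  }
}

# full rate law with the non-varied factors at their held levels
full_rate <- function(factor, channel, p, grid, held) {
  vapply(grid, function(v) {
    env_args <- list(temperature = held$temperature, I_av = held$I_av,
                     nitrogen = held$nitrogen, carbon = held$carbon)
    env_args[[if (factor == "light") "I_av" else factor]] <- v
    env <- do.call(culture_env, env_args)
    if (channel == "growth") specific_growth_rate(env, p)
    else carotene_rate(culture_state(X = 0.1, W = 0), env, p)
  }, numeric(1))
}

#' Generate a measured batch time course
#'
#' Simulates a batch under a cultivation condition, subsamples it at the
#' requested cadence and applies multiplicative noise to the biomass and
#' carotene channels independently. `replicates > 1` emits replicate columns
#' (`dw_g_per_l_1`, ...), mirroring triplicate experiments.
#'
#' @param cond A [cultivation_condition()].
#' @param p A [parameter_set()]; recorded as truth.
#' @param reactor A [reactor_config()].
#' @param sampling `"daily"` or `"hourly"`.
#' @param noise A [noise_model()].
#' @param replicates Number of replicate measurement columns.
#' @return Data frame `time_h`, `dw_g_per_l`, `bcar_frac` (suffixed when
#'   `replicates > 1`) with attributes `truth`, `condition`, `noise`.
#' @export
generate_time_course <- function(cond, p = carokin_preset("table1_prior"),
                                 reactor = reactor_config(),
                                 sampling = c("daily", "hourly"),
                                 noise = noise_model(cv = 0), replicates = 1L) {
  sampling <- match.arg(sampling)
  step <- if (sampling == "daily") 24 else 1
  times <- seq(0, cond$duration, by = step)
  traj <- simulate_batch(cond, p, reactor, times = times)
  out <- data.frame(time_h = traj$time_h)
  for (r in seq_len(replicates)) {
    sfx <- if (replicates > 1L) paste0("_", r) else ""
    nz <- noise
    nz$seed <- noise$seed + 1000L * (r - 1L)
    out[[paste0("dw_g_per_l", sfx)]] <- apply_noise(traj$dw_g_per_l, nz,
                                                   floor_at = TRUE)
    nz$seed <- nz$seed + 500L
    out[[paste0("bcar_frac", sfx)]] <- apply_noise(traj$bcar_frac, nz,
                                                  floor_at = TRUE)
  }
  structure(out, truth = p, condition = cond, noise = noise,
            class = c("measured_timecourse", "data.frame"))
}

#' Validation batch conditions
#'
#' The four 6-day validation batches A-D: initial DW 0.1 g/L throughout,
#' photoperiods 14:10 / 24:0 / 24:0 / 14:10, temperatures 20 / 25 / 20 /
#' 25 C, incident light 200 / 600 / 800 / 1000 umol photons m-2 s-1, carbon
#' 5 / 5 / 200 / 200 mM and nitrate 50 / 500 / 50 / 500 mg/L.
#'
#' @return Named list of four [cultivation_condition()] objects.
#' @export
preset_conditions <- function() {
  list(
    A = cultivation_condition(0.1, c(14, 10), 20, 200, 5, 50, 144, label = "A"),
    B = cultivation_condition(0.1, c(24, 0), 25, 600, 5, 500, 144, label = "B"),
    C = cultivation_condition(0.1, c(24, 0), 20, 800, 200, 50, 144, label = "C"),
    D = cultivation_condition(0.1, c(14, 10), 25, 1000, 200, 500, 144, label = "D"))
}
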