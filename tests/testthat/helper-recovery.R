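# Round-trip recovery helpers: generate a noise-free synthetic dataset from
# the prior preset, fit the relevant sub-model, return the recovered
# constants. Shared by the unit tests and the acceptance checks.

recover_light_growth <- function(seed = 1L) {
  p <- carokin_preset("table1_prior")
  d <- generate_single_factor_dataset("light", "growth", p,
                                      grid = seq(0, 2000, length.out = 24),
                                      hold_at_unity = TRUE)
  fit <- fit_single_factor_curve("aiba", d,
                                 fit_config(seed = seed, multi_start = 10L))
  fit$parameters  # a (= mu_max), K_s, K_i
}

recover_monod_growth <- function(factor, seed = 1L) {
  p <- carokin_preset("table1_prior")
  d <- generate_single_factor_dataset(factor, "growth", p,
                                      grid = seq(0, 500, length.out = 24),
                                      hold_at_unity = TRUE)
  fit <- fit_single_factor_curve("monod", d,
                                 fit_config(seed = seed, multi_start = 10L))
  fit$parameters  # a, K
}

recover_light_carotene <- function(seed = 1L) {
  p <- carokin_preset("table1_prior")
  d <- generate_single_factor_dataset("light", "carotene", p,
                                      grid = seq(0, 2000, length.out = 24),
                                      held = culture_env(10, 600, 500, 200))
  fit <- fit_single_factor_curve("aiba", d,
                                 fit_config(seed = seed, multi_start = 10L))
  fit$parameters  # a (env scale), K_s (= K_sw), K_i (= K_iw)
}

recover_nitrogen_carotene <- function(seed = 1L) {
  p <- carokin_preset("table1_prior")
  held <- culture_env(10, 600, 500, 200)
  d <- generate_single_factor_dataset("nitrogen", "carotene", p,
                                      grid = seq(20, 1000, length.out = 24),
                                      held = held)
  # the designed experiment knows its non-varied factor product
  w <- p$carotene
  scale <- (1 - w$K_CW / held$carbon) * (w$K_CW / held$carbon) *
    light_factor(held$I_av, w$K_sw, w$K_iw) *
    temperature_factor(held$temperature + 273.15, w$A_w, w$B_w,
                       w$E_aw, w$E_bw, p$R)
  fit <- fit_single_factor_curve("carotene_nitrogen", d,
                                 fit_config(seed = seed, multi_start = 10L),
                                 fixed = c(a = scale))
  fit$parameters  # a (fixed), K (= K_NW), b
}

recover_wmax <- function(seed = 1L) {
  p <- carokin_preset("table1_prior")
  cond <- cultivation_condition(initial_DW = 0.1, photoperiod = c(24, 0),
                                temperature = 10, light = 600, carbon = 200,
                                nitrogen = 500, duration = 400,
                                initial_W = 0.01, label = "w_max round trip")
  tc <- generate_time_course(cond, p, reactor_config(mode = "incident"),
                             sampling = "hourly")
  fit <- fit_content_curve(tc$time_h, tc$bcar_frac,
                           fit_config(seed = seed, multi_start = 10L))
  fit$parameters  # r, w_max
}

recover_mud <- function(seed = 1L) {
  p <- carokin_preset("table1_prior")
  cond <- cultivation_condition(initial_DW = 0.1, photoperiod = c(24, 0),
                                temperature = 25, light = 600, carbon = 50,
                                nitrogen = 500, duration = 300,
                                label = "decay round trip")
  tc <- generate_time_course(cond, p, reactor_config(mode = "incident"),
                             sampling = "hourly")
  fit <- fit_growth_curve(tc$time_h, tc$dw_g_per_l,
                          fit_config(seed = seed, multi_start = 10L))
  fit$parameters  # mu0, mu_d
}

# two-batch design that makes the growth half-velocity constants
# identifiable from biomass time courses: one nitrate-limited, one
# carbon-limited culture
kn_kc_experiments <- function(p) {
  conds <- list(
    cultivation_condition(0.1, c(24, 0), 25, 600, carbon = 50, nitrogen = 10,
                          duration = 144, label = "N-limited"),
    cultivation_condition(0.1, c(24, 0), 25, 600, carbon = 0.5, nitrogen = 500,
                          duration = 144, label = "C-limited"))
  lapply(conds, function(cn) {
    tc <- suppressWarnings(
      generate_time_course(cn, p, reactor_config(mode = "incident"),
                           sampling = "daily"))
    batch_experiment(cn, as.data.frame(tc))
  })
}
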