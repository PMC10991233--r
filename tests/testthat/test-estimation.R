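test_that("objective is zero on self-generated data and matches hand arithmetic", {
  p <- carokin_preset("table1_prior")
  conds <- preset_conditions()[c("C", "D")]
  exps <- lapply(conds, function(cn) {
    tc <- generate_time_course(cn, p, sampling = "daily")
    batch_experiment(cn, as.data.frame(tc))
  })
  expect_lt(relative_error_objective(p, exps), 1e-5)

  # obs = 2 * sim everywhere -> mean |s - 2s| / 2s = 0.5
  doubled <- lapply(exps, function(ex) {
    ex$observed$dw_g_per_l <- 2 * ex$observed$dw_g_per_l
    ex$observed$bcar_frac <- 2 * ex$observed$bcar_frac
    ex
  })
  expect_equal(relative_error_objective(p, doubled), 0.5, tolerance = 1e-6)

  # channel weights can silence a channel
  expect_equal(relative_error_objective(p, doubled,
                                        weights = c(dw_g_per_l = 1, bcar_frac = 0)),
               0.5, tolerance = 1e-6)
})

test_that("single-factor curve fits recover the generating constants within 1%", {
  th_a <- recover_light_growth(seed = 1L)
  expect_close(th_a[["a"]], 0.1608, rel = 0.01)
  expect_close(th_a[["K_s"]], 379.6, rel = 0.01)
  expect_close(th_a[["K_i"]], 1705, rel = 0.01)

  th_n <- recover_monod_growth("nitrogen", seed = 1L)
  expect_close(th_n[["K"]], 9.88, rel = 0.01)
  th_c <- recover_monod_growth("carbon", seed = 1L)
  expect_close(th_c[["K"]], 0.22, rel = 0.01)

  th_w <- recover_light_carotene(seed = 1L)
  expect_close(th_w[["K_s"]], 580, rel = 0.01)
  expect_close(th_w[["K_i"]], 936.5, rel = 0.01)

  th_kn <- recover_nitrogen_carotene(seed = 1L)
  expect_close(th_kn[["K"]], 43.37, rel = 0.01)
  expect_close(th_kn[["b"]], 0.03, rel = 0.01)
})

test_that("time-course fits recover the ceiling and decay constants", {
  th_w <- recover_wmax(seed = 1L)
  expect_close(th_w[["w_max"]], 0.039, rel = 0.01)
  th_d <- recover_mud(seed = 1L)
  expect_close(th_d[["mu_d"]], 0.3, rel = 0.01)
  # the fitted mu0 agrees with the rate law evaluated at the condition
  p <- carokin_preset("table1_prior")
  mu0 <- specific_growth_rate(culture_env(25, 600, 500, 50), p)
  expect_close(th_d[["mu0"]], mu0, rel = 0.01)
})

test_that("noisy recovery stays within 10% median error over 20 seeds", {
  p <- carokin_preset("table1_prior")
  errs <- vapply(1:20, function(s) {
    d <- generate_single_factor_dataset("nitrogen", "growth", p,
                                        grid = seq(0, 500, length.out = 24),
                                        hold_at_unity = TRUE,
                                        noise = noise_model(cv = 0.05, seed = s))
    fit <- fit_single_factor_curve("monod", d, fit_config(seed = s))
    abs(fit$parameters[["K"]] - 9.88) / 9.88
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("flat responses trigger a non-identifiability warning with zero objective", {
  d <- data.frame(factor_value = seq(1, 100, length.out = 10),
                  rate = rep(0, 10))
  expect_warning(fit <- fit_single_factor_curve("monod", d), "identifiab")
  expect_equal(fit$objective, 0)
  expect_false(fit$converged)
})

test_that("PSO recovers the minimum of a convex quadratic and is bit-reproducible", {
  quad <- function(th) (th[["u"]] - 3)^2 + 2 * (th[["v"]] + 1)^2 + 0.5
  cfg <- fit_config(swarm_size = 20L, max_iterations = 60L, seed = 11L,
                    bounds = list(u = c(-10, 10), v = c(-10, 10)))
  fit <- pso_optimize(cfg = cfg, initial = c(u = 0, v = 0), objective = quad)
  expect_lt(abs(fit$parameters[["u"]] - 3), 1e-3)
  expect_lt(abs(fit$parameters[["v"]] + 1), 1e-3)
  expect_equal(fit$objective, 0.5, tolerance = 1e-6)
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$objective, quad(c(u = 0, v = 0)))

  fit2 <- pso_optimize(cfg = cfg, initial = c(u = 0, v = 0), objective = quad)
  expect_identical(fit$parameters, fit2$parameters)
  expect_identical(fit$trace, fit2$trace)
})

test_that("PSO round-trips the growth half-velocity constants from batch data", {
  p <- carokin_preset("table1_prior")
  exps <- kn_kc_experiments(p)
  start <- update_parameters(p, c(K_N = 6, K_C = 0.4))
  cfg <- fit_config(free_parameters = c("K_N", "K_C"),
                    bounds = list(K_N = c(9.88 / 2, 9.88 * 2),
                                  K_C = c(0.22 / 2, 0.22 * 2)),
                    swarm_size = 12L, max_iterations = 25L, seed = 5L)
  fit <- pso_optimize(exps, cfg, start,
                      reactor = reactor_config(mode = "incident"),
                      weights = c(dw_g_per_l = 1, bcar_frac = 0))
  expect_close(fit$estimates[["K_N"]], 9.88, rel = 0.02)
  expect_close(fit$estimates[["K_C"]], 0.22, rel = 0.02)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("infeasible swarms and out-of-bounds starts fail with clear messages", {
  cfg <- fit_config(bounds = list(u = c(0, 1)), swarm_size = 5L,
                    max_iterations = 3L)
  expect_error(pso_optimize(cfg = cfg, initial = c(u = 5),
                            objective = function(th) th[["u"]]),
               "outside the bounds")
  expect_error(pso_optimize(cfg = cfg, initial = c(u = 0.5),
                            objective = function(th) Inf),
               "infeasible")
})

test_that("sensitivity scan re-evaluates reproducibly and collapses at zeta = 0", {
  p <- carokin_preset("table1_prior")
  cond <- preset_conditions()$C
  tc <- generate_time_course(cond, p, sampling = "daily")
  exps <- list(batch_experiment(cond, as.data.frame(tc)))

  rep1 <- sensitivity_scan(p, exps, Q = 5L, zeta = 0.05, seed = 3L,
                           parameters = c("K_s", "mu_max", "w_max"))
  rep2 <- sensitivity_scan(p, exps, Q = 5L, zeta = 0.05, seed = 3L,
                           parameters = c("K_s", "mu_max", "w_max"))
  expect_identical(rep1$draws, rep2$draws)
  expect_equal(nrow(rep1$draws), 15L)  # Q entries per parameter

  rep0 <- sensitivity_scan(p, exps, Q = 4L, zeta = 0, seed = 3L,
                           parameters = "K_s")
  expect_length(unique(rep0$draws$objective), 1L)

  # true parameters are optimal on their own noise-free data
  expect_true(all(rep1$min_at_zero))
})
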