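test_that("temperature factor matches term-by-term evaluation and cancels when terms match", {
  # identical activation and inactivation terms cancel exactly
  expect_equal(temperature_factor(300, 2, 2, 1.5, 1.5), 0)

  # optimized growth block at 25 C, against an independent term-by-term product
  expected <- 22.6350 * exp(-1.0026 / (8.3145e-3 * 298.15)) -
    17.4630 * exp(-0.5572 / (8.3145e-3 * 298.15))
  expect_equal(temperature_factor(298.15, 22.6350, 17.4630, 1.0026, 0.5572),
               expected, tolerance = 1e-12)
  expect_lt(abs(expected - 1.158), 1e-3)

  # prior carotene block at 10 C
  fw <- temperature_factor(283.15, 0.4355, 0.35, 5.286, 6.069)
  expect_lt(abs(fw - 0.0195), 1e-4)

  expect_error(temperature_factor(-1, 1, 1, 1, 1), "absolute temperature")
})

test_that("temperature factor is finite and continuous over 0-60 C for both presets", {
  grid <- seq(273.15, 333.15, by = 0.05)
  for (preset in c("table1_prior", "table2_optimized")) {
    g <- carokin_preset(preset)$growth
    f <- temperature_factor(grid, g$A, g$B, g$E_a, g$E_b)
    expect_true(all(is.finite(f)))
    expect_lt(max(abs(diff(f))), 1e-3)  # no jumps at 0.05 K resolution
  }
})

test_that("Aiba light factor has its closed-form maximum at sqrt(K_s K_i)", {
  expect_equal(light_factor(0, 379.6, 1705), 0)
  expect_lt(abs(light_factor(600, 379.6, 1705) - 0.5039), 2e-4)

  cases <- list(c(379.6, 1705), c(580, 936.5), c(10, 5000), c(200, 250))
  for (ks_ki in cases) {
    K_s <- ks_ki[1]; K_i <- ks_ki[2]
    opt <- optimal_light(K_s, K_i)
    expect_equal(light_factor(opt$I_opt, K_s, K_i), opt$f_max,
                 tolerance = 1e-12)
    grid <- seq(0, 10 * opt$I_opt, length.out = 4001)
    f <- light_factor(grid, K_s, K_i)
    step <- grid[2] - grid[1]
    expect_lt(abs(grid[which.max(f)] - opt$I_opt), step + 1e-9)
    expect_lt(abs(max(f) - opt$f_max), 1e-6)
    expect_true(all(f >= 0 & f < 1))
  }
  expect_error(light_factor(-5, 100, 1000), "I_av")
})

test_that("Monod factor obeys half-saturation identity and is monotone in [0,1)", {
  expect_equal(substrate_factor(9.88, 9.88), 0.5)
  expect_equal(substrate_factor(0, 3), 0)
  expect_lt(abs(substrate_factor(500, 9.88) - 0.9806), 1e-4)
  for (K in c(0.22, 9.88, 43.37)) {
    s <- seq(0, 1000, length.out = 500)
    f <- substrate_factor(s, K)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f < 1))
  }
  expect_error(substrate_factor(-1, 2), "S must be")
})

test_that("specific growth rate is the product of its factors", {
  p <- carokin_preset("table2_optimized")
  expect_equal(specific_growth_rate(culture_env(25, 0, 500, 200), p), 0)

  env <- culture_env(25, 600, 500, 200)
  g <- p$growth
  oracle <- g$mu_max *
    (g$A * exp(-g$E_a / (R_GAS * 298.15)) - g$B * exp(-g$E_b / (R_GAS * 298.15))) *
    (600 / (600 + g$K_s + 600^2 / g$K_i)) *
    (200 / (g$K_C + 200)) * (500 / (g$K_N + 500))
  expect_equal(specific_growth_rate(env, p), oracle, tolerance = 1e-12)

  # saturating substrates at the optimal light: mu_max f(T) / (1 + 2 sqrt(Ks/Ki))
  I_opt <- sqrt(g$K_s * g$K_i)
  env_sat <- culture_env(25, I_opt, 1e9, 1e9)
  fT <- temperature_factor(298.15, g$A, g$B, g$E_a, g$E_b)
  limit <- g$mu_max * fT / (1 + 2 * sqrt(g$K_s / g$K_i))
  expect_equal(specific_growth_rate(env_sat, p), limit, tolerance = 1e-6)
})

test_that("biomass rate has roots at zero and at mu0/mu_d", {
  expect_equal(biomass_rate(0, 0.164, 0.3), 0)
  expect_equal(biomass_rate(0.164 / 0.3, 0.164, 0.3), 0, tolerance = 1e-15)
  expect_equal(biomass_rate(0.1, 0.164, 0.3), 0.164 * 0.1 - 0.3 * 0.01)
  expect_error(biomass_rate(-0.1, 0.1, 0.3), "X must be")
  # exactly one interior crossing beyond the root at X = 0 when mu0 > 0
  X <- seq(1e-6, 2, length.out = 20001)
  r <- biomass_rate(X, 0.164, 0.3)
  expect_equal(sum(diff(sign(r)) != 0), 1L)
})

test_that("carotene rate law matches term-by-term evaluation and its structural zeros", {
  p <- carokin_preset("table1_prior")
  w <- p$carotene
  env <- culture_env(10, 600, 500, 200)

  expect_equal(carotene_rate(culture_state(0.1, w$w_max), env, p), 0)
  env_kcw <- culture_env(10, 600, 500, w$K_CW)
  expect_equal(carotene_rate(culture_state(0.1, 0.01), env_kcw, p), 0)

  oracle <- (w$b + (1 - w$K_NW / 500)) * (w$K_NW / 500) *
    (1 - w$K_CW / 200) * (w$K_CW / 200) * 1 *
    (600 / (600 + w$K_sw + 600^2 / w$K_iw)) *
    (w$A_w * exp(-w$E_aw / (R_GAS * 283.15)) -
       w$B_w * exp(-w$E_bw / (R_GAS * 283.15)))
  got <- carotene_rate(culture_state(0.1, 0), env, p)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(abs(got - 3.0e-5), 1e-6)

  # affine decreasing in W at fixed environment
  Ws <- seq(0, w$w_max, length.out = 7)
  rates <- vapply(Ws, function(wv)
    carotene_rate(culture_state(0.1, wv), env, p), numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_equal(diff(rates, lag = 1), rep(diff(rates)[1], 6), tolerance = 1e-10)

  expect_error(carotene_rate(culture_state(0.1, 0), culture_env(10, 600, 0, 200), p),
               "nitrogen and carbon")
  expect_error(carotene_rate(culture_state(0.1, 0.05), env, p), "exceeds w_max")
})

test_that("parameter sets validate invariants and round-trip JSON bit-exactly", {
  expect_error(growth_parameters(0.16, 0.3, 1705, 379.6, 9.88, 0.22,
                                 15, 15, 0.6, 0.6), "K_i must exceed")
  expect_error(growth_parameters(-0.1, 0.3, 379.6, 1705, 9.88, 0.22,
                                 15, 15, 0.6, 0.6), "strictly positive")
  expect_error(carotene_parameters(1.5, 0.03, 43, 10, 580, 936, 0.4, 0.35,
                                   5.3, 6.1), "mass fraction")

  for (preset in c("table1_prior", "table2_optimized")) {
    p <- carokin_preset(preset)
    path <- withr::local_tempfile(fileext = ".json")
    write_parameters(p, path)
    p2 <- read_parameters(path)
    expect_identical(flatten_parameters(p), flatten_parameters(p2))
  }

  # unknown or missing symbols are rejected by name
  flat <- flatten_parameters(carokin_preset("table1_prior"))
  expect_error(unflatten_parameters(flat[-1]), "missing")
  expect_error(unflatten_parameters(c(flat, bogus = 1)), "unknown parameter")
})

test_that("preset values reproduce the published tables exactly", {
  f1 <- flatten_parameters(carokin_preset("table1_prior"))
  expect_identical(unname(f1[c("K_s", "K_i", "K_N", "K_C", "mu_max", "mu_d")]),
                   c(379.6, 1705, 9.88, 0.22, 0.1608, 0.3))
  expect_identical(unname(f1[c("K_sw", "K_iw", "K_NW", "K_CW", "w_max", "b")]),
                   c(580, 936.5, 43.37, 10.38, 0.039, 0.03))
  f2 <- flatten_parameters(carokin_preset("table2_optimized"))
  expect_identical(unname(f2[c("K_s", "E_a", "E_b", "mu_max", "mu_d", "w_max")]),
                   c(384.9, 1.0026, 0.5572, 0.20278, 0.15, 0.0405))
})

test_that("environment guard bands reject unphysical conditions", {
  expect_error(culture_env(temperature = 80), "guard band")
  expect_error(culture_env(I_av = -1), "I_av")
  expect_error(culture_state(-1, 0), "X must be")
})
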