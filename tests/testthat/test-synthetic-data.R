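test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(42, "multiplicative", 0.01)
  p <- vft_parameters(-12.57, 1346, 223.1)
  s1 <- make_bds_series(p, bds_temperature_grid(p, n = 5), cfg = cfg)
  s2 <- make_bds_series(p, bds_temperature_grid(p, n = 5), cfg = cfg)
  expect_identical(s1, s2)
  reg <- component_registry()
  d1 <- make_dsc(reg[c("EZB", "FEN")], c(0.3, 0.7), cfg = cfg)
  d2 <- make_dsc(reg[c("EZB", "FEN")], c(0.3, 0.7), cfg = cfg)
  expect_identical(d1, d2)
  c1 <- make_crystallization(4000, cfg = cfg)
  c2 <- make_crystallization(4000, cfg = cfg)
  expect_identical(c1, c2)
  # different seed changes the noise
  c3 <- make_crystallization(4000, cfg = generator_config(43,
                                                          "multiplicative",
                                                          0.01))
  expect_false(identical(c1$eps_static, c3$eps_static))
})

test_that("DSC generator ground truth matches its phase diagram", {
  reg <- component_registry()
  comps <- reg[c("EZB", "SVT", "FEN")]
  mm <- vapply(comps, `[[`, 0, "molar_mass")
  eut <- ternary_eutectic(comps[[1]], comps[[2]], comps[[3]], surface = FALSE)
  # at the eutectic composition: exactly one endotherm by construction
  tg_e <- make_dsc(comps, eut$x_e, cfg = generator_config(1, "none"))
  expect_equal(attr(tg_e, "ground_truth")$n_events, 1L)
  # off-eutectic binary: two events, recovered within 0.5 K
  x2 <- weight_to_mole(c(0.3, 0.7), mm[c("EZB", "FEN")])
  tg_b <- make_dsc(comps[c("EZB", "FEN")], x2,
                   cfg = generator_config(2, "none"))
  gt <- attr(tg_b, "ground_truth")
  expect_equal(gt$n_events, 2L)
  ev <- detect_endotherms(tg_b)
  expect_equal(nrow(ev), 2L)
  expect_true(all(abs(ev$onset_K - gt$events$onset_K) < 0.5))
  # doubling the heating rate shifts peaks up by the configured lag
  tg_fast <- make_dsc(comps[c("EZB", "FEN")], x2, rate = 20,
                      cfg = generator_config(2, "none"))
  expect_equal(attr(tg_fast, "ground_truth")$events$peak_K -
                 gt$events$peak_K,
               rep(0.15 * 10, 2))
})

test_that("BDS generator spectra carry the prescribed relaxation times", {
  p <- vft_parameters(-12.57, 1346, 223.1)
  series <- make_bds_series(p, bds_temperature_grid(p, n = 7),
                            cfg = generator_config(3, "none"))
  gt <- attr(series, "ground_truth")
  expect_equal(gt$map$tau_alpha_s,
               vft_tau(gt$map$temperature_K, p), tolerance = 1e-12)
  # the spectra themselves peak where the prescribed tau_alpha says
  for (i in c(1, 4, 7)) {
    sp <- series[[i]]
    fpk <- sp$frequency[which.max(sp$eps_imag)]
    expect_equal(1 / (2 * pi * fpk), gt$map$tau_alpha_s[i],
                 tolerance = 0.3)  # grid-resolution agreement
  }
})

test_that("full dielectric chain round-trips the generating VFT law", {
  p <- vft_parameters(-12.55, 1280, 219.0)
  series <- make_bds_series(p, bds_temperature_grid(p),
                            cfg = generator_config(4, "none"))
  taus <- vapply(series, function(s) fit_hn(s)$tau_alpha, 0)
  Ts <- vapply(series, `[[`, 0, "temperature")
  fit <- fit_vft(relaxation_map(Ts, taus))
  expect_equal(fit$B, p$B, tolerance = 5e-4)
  expect_equal(fit$T0_vogel, p$T0_vogel, tolerance = 5e-4)
  expect_lt(abs(fit$log10_tau_inf - p$log10_tau_inf), 5e-3)
  # Debye-shaped generation: refitted exponents return to 1
  sd <- make_bds_series(p, bds_temperature_grid(p, n = 3),
                        cfg = generator_config(5, "none"),
                        shape = list(a = 1, b = 1))
  fd <- fit_hn(sd[[2]])
  expect_lt(abs(fd$parameters$a - 1), 1e-3)
  expect_lt(abs(fd$parameters$b - 1), 1e-3)
})

test_that("two-regime series expose their construction crossover", {
  p1 <- vft_parameters(-12.51, 1483, 266.5)
  # place the crossover where tau ~ 1e-4 s so both regimes keep their loss
  # peaks inside the measurement window
  T_cross <- kinetic_tg(p1, tau_ref = 1e-4)
  p2 <- vft_second_regime(p1, T_cross = T_cross, B2 = 3 * p1$B)
  Tlo <- bds_temperature_grid(p1, log10_tau_range = c(-1.5, -3.7), n = 8)
  Thi <- bds_temperature_grid(p2, log10_tau_range = c(-4.3, -6.5), n = 8)
  series <- make_bds_series(p1, c(Tlo, Thi), vft2 = p2, T_cross = T_cross,
                            cfg = generator_config(6, "none"))
  taus <- vapply(series, function(s) fit_hn(s)$tau_alpha, 0)
  Ts <- vapply(series, `[[`, 0, "temperature")
  cr <- detect_crossover(stickel_transform(relaxation_map(Ts, taus)))
  expect_false(is.na(cr$T_cross))
  expect_lt(abs(cr$T_cross - T_cross), 3)
})

test_that("crystallization generator hits its half-life exactly at zero noise", {
  cs <- make_crystallization(7200, avrami_n = 3, eps0 = 9, epsinf = 4,
                             step = 600, cfg = generator_config(9, "none"))
  gt <- attr(cs, "ground_truth")
  eps_at_half <- gt$epsinf + (gt$eps0 - gt$epsinf) * 0.5
  expect_equal(stats::approx(cs$time, cs$eps_static, xout = 7200)$y,
               eps_at_half, tolerance = 1e-6)
})
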