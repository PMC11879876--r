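# GSER, Green-Kubo, stretched-exponential and scaling fits.

test_that("MSD computation: linear, static and diffusive tracks", {
  t <- seq_len(500) * 0.1
  lin <- cbind(2 * t, 0 * t, -t)
  m <- compute_msd(lin, dt = 0.1, a = 1)
  expect_equal(m$msd, 5 * m$t^2, tolerance = 1e-9)
  static <- matrix(3, 500, 3)
  expect_true(all(compute_msd(static, dt = 0.1)$msd == 0))
  # seeded random walk: slope 6D over mid lags
  set.seed(5)
  D <- 0.25
  steps <- matrix(stats::rnorm(3 * 20000, 0, sqrt(2 * D * 0.1)), ncol = 3)
  walk <- apply(steps, 2, cumsum)
  mw <- compute_msd(walk, dt = 0.1)
  sel <- mw$t > 1 & mw$t < 50
  slope <- stats::coef(stats::lm(mw$msd[sel] ~ mw$t[sel]))[2]
  expect_lt(abs(slope / (6 * D) - 1), 0.05)
})

test_that("GSER closed forms: viscous, trapped and half-power-law MSDs", {
  # pure diffusion: G'' = omega eta with eta = kT/(6 pi a D), G' ~ 0
  m <- make_trap_msd(k = 0, a = 2.5, noise = 0)
  sp <- gser_moduli(m)
  expect_lt(max(abs(sp$g2 / (sp$omega * attr(m, "eta_true")) - 1)), 0.02)
  expect_lt(max(sp$g1), 1e-10)
  # harmonic trap: plateau k/(6 pi a) at the low-frequency end
  k <- 1.7
  mt <- make_trap_msd(k = k, a = 2.5, noise = 0)
  spt <- gser_moduli(mt)
  expect_lt(abs(spt$g1[1] / (k / (6 * pi * 2.5)) - 1), 0.02)
  # MSD ~ t^(1/2): loss tangent is exactly 1 at all frequencies
  tt <- exp(seq(log(0.01), log(100), length.out = 60))
  sph <- gser_moduli(msd_series(tt, 6 * sqrt(tt), a = 2.5))
  expect_lt(max(abs(sph$g2 / sph$g1 - 1)), 0.02)
})

test_that("noisy trap MSD still yields the plateau within 10%", {
  k <- 1
  mt <- make_trap_msd(k = k, a = 2.5, noise = 0.05, seed = 8)
  spt <- gser_moduli(mt)
  keep <- which(!spt$masked)
  # plateau read in the low-frequency (plateaued-MSD) decade
  low <- keep[seq_len(min(8, length(keep)))]
  expect_lt(abs(stats::median(spt$g1[low]) / (k / (6 * pi * 2.5)) - 1), 0.1)
})

test_that("Green-Kubo on OU stress reproduces the closed-form relaxation", {
  st <- make_ou_stress(A = 2, tau_c = 1, n = 2e5, dt = 0.01, seed = 4)
  gk <- green_kubo_relaxation(st, max_lag_frac = 0.003)
  sel <- gk$t <= 3
  expect_lt(max(abs(gk$g[sel] - 2 * exp(-gk$t[sel]))) / 2, 0.1)
  # zero stress -> zero modulus
  z <- stress_series(seq_len(200) * 0.1, matrix(0, 200, 3), volume = 5)
  expect_true(all(green_kubo_relaxation(z)$g == 0))
  # white noise decorrelates after one sampling interval
  set.seed(2)
  w <- stress_series(seq_len(5e4) * 0.1, matrix(stats::rnorm(15e4), ncol = 3),
                     volume = 1)
  gw <- green_kubo_relaxation(w, max_lag_frac = 0.01)
  expect_lt(max(abs(gw$g[-1])), 0.05 * gw$g[1])
})

test_that("stretched-exponential fits recover generating parameters", {
  tt <- seq(0.1, 30, length.out = 50)
  f <- fit_stretched_exponential(list(t = tt, g = 2 * exp(-tt / 5)))
  expect_equal(c(f$a, f$tau, f$b), c(2, 5, 1), tolerance = 1e-6)
  set.seed(11)
  g2 <- 1.5 * exp(-(tt / 3)^0.6) * (1 + 0.01 * stats::rnorm(50))
  f2 <- fit_stretched_exponential(list(t = tt, g = g2))
  expect_lt(abs(f2$a / 1.5 - 1), 0.05)
  expect_lt(abs(f2$tau / 3 - 1), 0.05)
  expect_lt(abs(f2$b / 0.6 - 1), 0.05)
  expect_error(fit_stretched_exponential(list(t = tt, g = tt)), "decay")
})

test_that("plateau and crossover extraction on Maxwell and degenerate spectra", {
  om <- exp(seq(log(0.01), log(100), length.out = 80))
  G <- 3; tau <- 2
  maxwell <- structure(list(omega = om, g1 = G * om^2 * tau^2 / (1 + om^2 * tau^2),
                            g2 = G * om * tau / (1 + om^2 * tau^2),
                            alpha = rep(0.5, 80), masked = rep(FALSE, 80),
                            a = 2.5, kT = 1), class = "modulus_spectrum")
  pc <- extract_plateau_crossover(maxwell)
  expect_lt(abs(pc$omega0 * tau - 1), 0.01)
  expect_lt(abs(pc$plateau / G - 1), 0.001)
  expect_equal(pc$tau_u, 1 / pc$omega0)
  viscous <- structure(list(omega = om, g1 = 0 * om, g2 = om,
                            alpha = rep(1, 80), masked = rep(FALSE, 80),
                            a = 2.5, kT = 1), class = "modulus_spectrum")
  pv <- extract_plateau_crossover(viscous)
  expect_false(pv$crossover_found)
  single <- structure(list(omega = 1, g1 = 1, g2 = 1, alpha = 0.5,
                           masked = FALSE, a = 2.5, kT = 1),
                      class = "modulus_spectrum")
  expect_error(extract_plateau_crossover(single), "at least 2")
})

test_that("power-law fits recover exact and noisy slopes, with breakpoints", {
  suppressWarnings({
    pf <- fit_power_law(c(1, 2, 4, 8), 2 * c(1, 2, 4, 8)^3)
  })
  expect_equal(pf$segments$all$slope, 3, tolerance = 1e-9)
  set.seed(1)
  x <- exp(seq(log(1), log(10), length.out = 8))
  y <- x^2.5 * exp(stats::rnorm(8, 0, 0.1))
  pn <- fit_power_law(x, y)
  expect_lt(abs(pn$segments$all$slope - 2.5), 2 * pn$segments$all$slope_se)
  xb <- c(0.01, 0.02, 0.04, 0.056, 0.08, 0.1, 0.14)
  yb <- ifelse(xb <= 0.056, xb^-0.6, 0.056^(-0.6 + 0.9) * xb^-0.9)
  suppressWarnings(pb <- fit_power_law(xb, yb, breakpoint = 0.056))
  expect_equal(pb$segments$below$slope, -0.6, tolerance = 1e-6)
  expect_equal(pb$segments$above$slope, -0.9, tolerance = 1e-6)
  expect_error(fit_power_law(c(1, 2), c(-1, 2)), "positive")
})

test_that("scaling-exponent predictions are exact slope arithmetic", {
  p <- predict_scaling_exponents(nminloop_slope = c(1.0, 0.05),
                                 xi_slope = c(-0.84, 0.02),
                                 z_slope = c(1.4, 0.1),
                                 lmin_slope = c(0.1, 0.01))
  expect_equal(p$mesh_exponent, 1.0 + 3 * 0.84)
  expect_equal(p$link_exponent, 2.4)
  expect_equal(p$geometric_z_exponent, 1.3)
  expect_equal(p$mesh_exponent_se, sqrt(0.05^2 + 0.06^2))
  expect_equal(p$phantom_prefactor, 1 / 3)
  expect_error(predict_scaling_exponents(), "no constituent")
})
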