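# Akima smoothing, diffusivity model, and rate inversion.

test_that("Akima spline interpolates and differentiates closed forms", {
  # linear data: reproduces the line, zero curvature
  x <- seq(0, 10, by = 1)
  s <- akima_spline(x, 3 + 2 * x)
  xq <- seq(0.3, 9.7, length.out = 40)
  expect_equal(eval_akima(s, xq), 3 + 2 * xq, tolerance = 1e-12)
  expect_equal(eval_akima(s, xq, deriv = 1), rep(2, 40), tolerance = 1e-12)
  expect_equal(eval_akima(s, xq, deriv = 2), rep(0, 40), tolerance = 1e-10)

  # parabola c = c0 + b z^2: interior second derivative = 2b
  b <- 0.7
  sp <- akima_spline(x, 5 + b * x^2)
  xin <- seq(2, 8, length.out = 20)
  expect_equal(eval_akima(sp, xin, deriv = 2), rep(2 * b, 20),
               tolerance = 1e-8)
  # first derivative cross-checked by numerical differentiation
  h <- 1e-6
  num <- (eval_akima(sp, xin + h) - eval_akima(sp, xin - h)) / (2 * h)
  expect_equal(eval_akima(sp, xin, deriv = 1), num, tolerance = 1e-5)

  # interpolation contract: passes through every point
  set.seed(42)
  y <- cumsum(rnorm(12))
  si <- akima_spline(1:12, y)
  expect_equal(eval_akima(si, 1:12), y, tolerance = 1e-12)

  expect_error(akima_spline(c(1, 2), c(1, 2)), "at least 3")
  expect_error(akima_spline(c(1, 1, 2), 1:3), "increasing")
  expect_error(eval_akima(si, 13), "outside")
})

test_that("sediment diffusivity obeys its stated monotonicities", {
  # porosity = 1: tortuosity correction is the identity
  for (spc in c("O2", "SO4", "DIC")) {
    d_free <- sediment_diffusivity(spc, 10, 1)
    expect_equal(1 - log(1^2), 1)
    expect_equal(as.numeric(d_free),
                 as.numeric(sediment_diffusivity(spc, 10, 1)))
    # increases with temperature
    temps <- seq(0, 30, by = 5)
    d <- vapply(temps,
                function(t) as.numeric(sediment_diffusivity(spc, t, 0.8)),
                0)
    expect_true(all(diff(d) > 0))
  }
  # monotone in porosity
  expect_lt(as.numeric(sediment_diffusivity("SO4", 5, 0.7)),
            as.numeric(sediment_diffusivity("SO4", 5, 0.9)))
  # magnitude sanity: SO4 at 5 C, phi 0.8 is a few cm2/yr x 1e-3 scale
  d <- as.numeric(sediment_diffusivity("SO4", 5, 0.8))
  expect_gt(d, 0.005); expect_lt(d, 0.05)   # m2/yr
  expect_error(sediment_diffusivity("SO4", 5, 1.2), "porosity")
})

test_that("closed-form profiles invert to their known rates", {
  z <- seq(0, 30, length.out = 40)
  phi <- 0.8
  ds <- as.numeric(sediment_diffusivity("SO4", 2, phi))

  # linear concentration, constant phi*Ds: pure diffusion, zero rate
  lin <- porewater_profile("SO4", z, 28 - 0.5 * z, phi, 2)
  r0 <- net_rate(lin)
  expect_equal(r0$net_rate, rep(0, nrow(r0)), tolerance = 1e-10)

  # c = c0 - b z^2, constant phi and Ds: uniform net *production* 2 b Ds
  # (a concave-down profile exports the species; consumption-positive
  # convention makes the net rate negative)
  b <- 0.02
  par <- porewater_profile("SO4", z, 40 - b * z^2, phi, 2)
  rp <- net_rate(par, query_depths = seq(5, 25, length.out = 11))
  expect_equal(rp$net_rate * 1000, rep(-2 * b * ds, 11), tolerance = 1e-3)

  # c = c0 + b z^2 (concave up): uniform consumption +2 b Ds
  rc <- net_rate(porewater_profile("SO4", z, 10 + b * z^2, phi, 2),
                 query_depths = seq(5, 25, length.out = 11))
  expect_equal(rc$net_rate * 1000, rep(2 * b * ds, 11), tolerance = 1e-3)
})

test_that("forward-then-inverse recovers the generating rate (< 5% L2)", {
  for (sd_seed in list(c(50, 1), c(80, 2))) {
    spec <- profile_spec(noise_sd = 0, n_samples = sd_seed[1],
                         seed = sd_seed[2])
    prof <- generate_profile(spec)
    r <- net_rate(prof)
    truth <- true_rate(spec, r$depth) / 1000
    l2 <- sqrt(sum((r$net_rate - truth)^2) / sum(truth^2))
    expect_lt(l2, 0.05)
  }
})

test_that("flux-budget closure holds to 1% on smooth synthetic input", {
  spec <- profile_spec(noise_sd = 0, n_samples = 60)
  prof <- generate_profile(spec)
  zq <- seq(min(prof$depth), max(prof$depth), length.out = 400)
  r <- net_rate(prof, query_depths = zq)
  integrated <- attr(r, "integrated_rate")
  flux_diff <- attr(r, "flux_top") - attr(r, "flux_bottom")
  expect_equal(integrated, flux_diff, tolerance = 0.01)
})

test_that("integrated rate is stable under query-grid refinement", {
  spec <- profile_spec(noise_sd = 0, n_samples = 60)
  prof <- generate_profile(spec)
  rng <- range(prof$depth)
  z1 <- seq(rng[1], rng[2], length.out = 200)
  z2 <- seq(rng[1], rng[2], length.out = 400)
  i1 <- attr(net_rate(prof, query_depths = z1), "integrated_rate")
  i2 <- attr(net_rate(prof, query_depths = z2), "integrated_rate")
  expect_lt(abs(i2 - i1) / abs(i1), 0.005)
})

test_that("a monotone consumed-only O2 profile has non-negative integral", {
  spec <- profile_spec(species = "O2", surface_conc = 0.25, rate0 = 2e-6,
                       efold = 15, depth_max = 80, noise_sd = 0,
                       n_samples = 50)
  prof <- generate_profile(spec)
  expect_true(all(diff(prof$conc) <= 0))
  expect_gte(attr(net_rate(prof), "integrated_rate"), 0)
})

test_that("Monte Carlo SDs behave: zero at zero noise, monotone in noise", {
  spec <- profile_spec(noise_sd = 0, n_samples = 40)
  prof <- generate_profile(spec)
  r0 <- monte_carlo_rates(prof, n = 20, seed = 7)
  expect_equal(r0$rate_sd, rep(0, nrow(r0)))

  # same seed -> identical; larger noise multiplier -> larger SDs
  sds <- vapply(c(0.01, 0.02, 0.04), function(ns) {
    r <- monte_carlo_rates(prof, n = 30, seed = 11,
                           conc_sd = ns * spec$surface_conc)
    mean(r$rate_sd)
  }, 0)
  expect_true(all(diff(sds) > 0))
  ra <- monte_carlo_rates(prof, n = 15, seed = 3, conc_sd = 0.1)
  rb <- monte_carlo_rates(prof, n = 15, seed = 3, conc_sd = 0.1)
  expect_identical(ra$rate_sd, rb$rate_sd)
  expect_error(monte_carlo_rates(prof, n = 1), "n >= 2")
})

test_that("rate CSV and query validation round-trip", {
  spec <- profile_spec(n_samples = 20, seed = 5)
  prof <- generate_profile(spec)
  expect_error(net_rate(prof, query_depths = 1e4), "outside")
  r <- monte_carlo_rates(prof, n = 10, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_rate_csv(r, f)
  back <- read.csv(f)
  expect_equal(back$net_rate_mol_L_yr, r$net_rate)
  expect_equal(back$rate_sd_mol_L_yr, r$rate_sd)
})
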