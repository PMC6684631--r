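# Synthetic profile and grid generators, and their text I/O dialects.

test_that("zero consumption gives a flat noise-free profile", {
  spec <- profile_spec(rate0 = 0, noise_sd = 0, n_samples = 20)
  prof <- generate_profile(spec)
  expect_equal(prof$conc, rep(spec$surface_conc, 20), tolerance = 1e-12)
})

test_that("profiles are deterministic under seed and vary across seeds", {
  s1 <- profile_spec(seed = 42)
  expect_identical(generate_profile(s1), generate_profile(s1))
  s2 <- profile_spec(seed = 43)
  expect_false(identical(generate_profile(s1)$conc,
                         generate_profile(s2)$conc))
})

test_that("the forward model honours boundary conditions and porosity", {
  spec <- profile_spec(noise_sd = 0, n_samples = 30)
  prof <- generate_profile(spec)
  expect_equal(prof$conc[1], spec$surface_conc, tolerance = 1e-9)
  # zero-gradient bottom: last two samples nearly equal
  expect_lt(abs(prof$conc[30] - prof$conc[29]),
            1e-3 * abs(prof$conc[1] - prof$conc[30]) + 1e-12)
  expect_equal(prof$porosity,
               spec$porosity_surface * exp(-prof$depth / 1000))
  expect_equal(prof$temperature, 2 + 0.05 * prof$depth)
  expect_true(all(diff(prof$depth) > 0))
})

test_that("infeasible (over-consuming) specs are rejected", {
  spec <- profile_spec(surface_conc = 0.1, rate0 = 1, efold = 50,
                       depth_max = 100, noise_sd = 0)
  expect_error(generate_profile(spec), "infeasible")
})

test_that("an explicit rate table drives the forward model", {
  tab <- data.frame(depth = c(0, 20, 100), rate = c(5e-5, 1e-5, 0))
  spec <- profile_spec(rate_table = tab, noise_sd = 0, n_samples = 60)
  prof <- generate_profile(spec)
  r <- net_rate(prof)
  truth <- true_rate(spec, r$depth) / 1000
  l2 <- sqrt(sum((r$net_rate - truth)^2) / sum(truth^2))
  expect_lt(l2, 0.05)
})

test_that("negative noisy concentrations are clipped to zero", {
  spec <- profile_spec(species = "O2", surface_conc = 0.01, rate0 = 1e-7,
                       efold = 10, depth_max = 60, noise_sd = 2,
                       n_samples = 30, seed = 9)
  prof <- generate_profile(spec)
  expect_true(all(prof$conc >= 0))
  expect_true(any(prof$conc == 0))   # heavy noise must actually clip
})

test_that("profile CSV round-trips bit-faithfully enough to reuse", {
  prof <- generate_profile(profile_spec(n_samples = 15, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  back <- read_profile_csv(f)
  expect_equal(back$depth, prof$depth)
  expect_equal(back$conc, prof$conc)
  expect_equal(back$porosity, prof$porosity)
  expect_identical(attr(back, "species"), attr(prof, "species"))
})

test_that("synthetic grids respect ranges, smoothness and determinism", {
  spec <- grid_spec(resolution_deg = 10, smoothness = 3, seed = 21)
  g <- generate_grids(spec)
  expect_identical(dim(g$heatflow$values), c(18L, 36L))
  expect_true(all(g$heatflow$values >= 40 & g$heatflow$values <= 200))
  expect_true(all(g$age$values > 0))
  expect_true(grids_conformable <- isTRUE(all.equal(g$heatflow$lat_edges,
                                                    g$age$lat_edges)))
  # determinism
  g2 <- generate_grids(spec)
  expect_identical(g$thickness$values, g2$thickness$values)

  # smoothness: neighbouring-cell differences shrink as smoothness grows
  rough <- generate_grids(grid_spec(resolution_deg = 10, smoothness = 0.5,
                                    seed = 5))$heatflow$values
  smooth <- generate_grids(grid_spec(resolution_deg = 10, smoothness = 8,
                                     seed = 5))$heatflow$values
  nn_diff <- function(m) mean(abs(diff(m)))
  expect_lt(nn_diff(smooth), nn_diff(rough) / 4)

  # near-infinite smoothness: essentially constant fields
  g_const <- generate_grids(grid_spec(resolution_deg = 10,
                                      smoothness = 1e4, seed = 2))
  expect_lt(diff(range(g_const$heatflow$values)), 1e-6 * 160)

  # degenerate thickness range: all zeros -> every cell oxic-candidate
  g0 <- generate_grids(grid_spec(resolution_deg = 10,
                                 thickness_range = c(0, 0), seed = 1))
  expect_true(all(g0$thickness$values == 0))
  zones <- classify_zone(as.vector(g0$thickness$values),
                         rep(0, length(g0$thickness$values)))
  expect_true(all(zones == "oxic_to_basement"))

  expect_error(grid_spec(resolution_deg = 7), "divide 180")
  expect_error(grid_spec(age_range = c(0, 100)), "> 0")
})

test_that("ESRI ASCII grids round-trip", {
  g <- generate_grids(grid_spec(resolution_deg = 10, seed = 4))$thickness
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  back <- read_esri_ascii(f, units = "m")
  expect_equal(back$values, g$values)
  expect_equal(back$lat_edges, g$lat_edges)
  expect_equal(back$lon_edges, g$lon_edges)
  # NODATA cells survive as NA
  g$values[3, 7] <- NA
  write_esri_ascii(g, f)
  expect_true(is.na(read_esri_ascii(f)$values[3, 7]))
})
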