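# Geotherm, spherical integration, and redox-zonation classification.

test_that("isotherm depth matches one- and two-layer closed forms", {
  uni <- geotherm_params(t_seafloor = 2, k_sediment = 1, k_basement = 1)
  expect_equal(isotherm_depth(100, 0, uni), 1200)          # k dT / q
  expect_equal(isotherm_depth(100, 5000, uni), 1200)       # inside sediment
  expect_equal(isotherm_depth(200, 0, uni), 600)           # doubling q halves

  two <- geotherm_params(t_seafloor = 2, k_sediment = 1, k_basement = 2)
  # 500 m sediment at q = 100 mW/m2: 52 C at basement top, then
  # 2 * 70 / 0.1 = 1400 m in basement -> 1900 m total
  expect_equal(isotherm_depth(100, 500, two), 1900)

  # monotone: decreasing in q, increasing in conductivity
  q <- seq(50, 300, by = 50)
  d <- isotherm_depth(q, 300, two)
  expect_true(all(diff(d) < 0))
  expect_gt(isotherm_depth(100, 300, geotherm_params(k_sediment = 1.5)),
            isotherm_depth(100, 300, geotherm_params(k_sediment = 1.0)))
  expect_error(isotherm_depth(0, 100), "positive")
})

test_that("habitable thickness and pore column follow the stated model", {
  expect_equal(habitable_basement_thickness(1900, 500), 1400)
  expect_equal(habitable_basement_thickness(300, 500), 0)
  expect_equal(habitable_basement_thickness(1200, 0), 1200)

  expect_equal(basement_pore_column(1000), 75)    # 0.1*500 + 0.05*500
  expect_equal(basement_pore_column(5000), 75)    # capped at z_zero
  expect_equal(basement_pore_column(0), 0)
  expect_equal(basement_pore_column(250), 25)     # constant-phi segment
  expect_equal(basement_pore_column(750),
               50 + 0.1 * (250 - 250^2 / 1000))   # into the linear segment
  # never exceeds 75 m under the default model
  h <- seq(0, 4000, by = 10)
  expect_true(all(basement_pore_column(h) <= 75 + 1e-12))
  expect_true(all(diff(basement_pore_column(h)) >= -1e-12))
})

test_that("mean sedimentation rate is thickness over age", {
  expect_equal(mean_sedimentation_rate(500, 100), 5)
  expect_equal(mean_sedimentation_rate(0, 50), 0)
  expect_equal(mean_sedimentation_rate(700, 20), 35)  # SO4 boundary case
  expect_error(mean_sedimentation_rate(100, 0), "positive")
})

test_that("zone classification uses strict 'exceeds' boundaries", {
  expect_equal(as.character(classify_zone(600, 10)), "sulfate_depleted")
  expect_equal(as.character(classify_zone(100, 40)), "sulfate_depleted")
  expect_equal(as.character(classify_zone(100, 10)), "oxic_to_basement")
  expect_equal(as.character(classify_zone(300, 20)), "sulfate_to_basement")
  # boundary cells stay in the less-reduced category
  expect_equal(as.character(classify_zone(500, 35)), "sulfate_to_basement")
  expect_equal(as.character(classify_zone(150, 15)), "oxic_to_basement")
  # monotone: increasing thickness/rate never moves toward oxidized
  lv <- as.integer(classify_zone(c(100, 300, 600), c(10, 10, 10)))
  expect_true(all(diff(lv) >= 0))
  lv2 <- as.integer(classify_zone(c(100, 100, 100), c(5, 20, 40)))
  expect_true(all(diff(lv2) >= 0))
  # extreme thresholds: everything in the first applicable category
  inf_thr <- zone_thresholds(1e12, 1e12, 1e12, 1e12)
  expect_true(all(classify_zone(c(10, 1e6), c(1, 1e6), inf_thr) ==
                    "oxic_to_basement"))
})

test_that("spherical cell areas and volume integration match closed forms", {
  g <- geo_grid(matrix(1, 18, 36))           # constant 1 m, global 10-deg
  areas <- cell_areas(g)
  expect_equal(sum(areas), 4 * pi * 6371^2, tolerance = 1e-10)
  expect_equal(integrate_volume(g), 4 * pi * 6371^2 * 1e-3,
               tolerance = 1e-10)
  # hemispheric mask halves the constant-field integral
  mask <- geo_grid(rbind(matrix(0, 9, 36), matrix(1, 9, 36)))
  expect_equal(integrate_volume(g, mask), 2 * pi * 6371^2 * 1e-3,
               tolerance = 1e-10)
  # all-masked -> 0
  none <- geo_grid(matrix(0, 18, 36))
  expect_equal(integrate_volume(g, none), 0)
  expect_error(integrate_volume(g, geo_grid(matrix(1, 9, 18))),
               "co-registered")
})

test_that("zone areas partition the (masked) seafloor", {
  g <- generate_grids(grid_spec(resolution_deg = 10, seed = 77))
  za <- zone_areas(g$thickness, g$age)
  expect_equal(sum(za$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(za$area_km2), 4 * pi * 6371^2, tolerance = 1e-9)

  # single-category grid: all area in that category
  flat_th <- geo_grid(matrix(1000, 18, 36))
  old_age <- geo_grid(matrix(100, 18, 36))
  za1 <- zone_areas(flat_th, old_age)
  expect_equal(za1$fraction[za1$zone == "sulfate_depleted"], 1)

  # masked fractions still partition to 1
  mask <- geo_grid(matrix(rep(c(0, 1), 18 * 18), 18, 36))
  zam <- zone_areas(g$thickness, g$age, ocean_mask = mask)
  expect_equal(sum(zam$fraction), 1, tolerance = 1e-12)
  expect_lt(sum(zam$area_km2), sum(za$area_km2))
})

test_that("habitable_volume composes the per-cell operations", {
  g <- generate_grids(grid_spec(resolution_deg = 10, seed = 31))
  hv <- habitable_volume(g$heatflow, g$thickness)
  manual_iso <- isotherm_depth(g$heatflow$values, g$thickness$values)
  expect_equal(hv$isotherm_depth$values, manual_iso)
  expect_gte(hv$rock_volume_km3, hv$pore_volume_km3)
  expect_gt(hv$pore_volume_km3, 0)
  # pore volume can never exceed 75 m times the ocean area
  expect_lt(hv$pore_volume_km3, 0.075 * 4 * pi * 6371^2)
})
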