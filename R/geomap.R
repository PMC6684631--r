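# Conductive geotherm, habitable-volume integration, and redox-zonation
# classification of the seafloor.

#' Conductive geotherm parameters
#'
#' Two-layer, steady-state, purely vertical conductive geotherm: the
#' temperature rises at `q/k_sediment` through the sediment and at
#' `q/k_basement` below. Defaults are documented configuration choices.
#'
#' @param t_seafloor Seafloor temperature (degrees C, default 2).
#' @param k_sediment Sediment thermal conductivity (W/m/K, default 1.0).
#' @param k_basement Basement thermal conductivity (W/m/K, default 2.0).
#' @param t_limit Temperature limit of life (degrees C, default 122, the
#'   currently accepted upper limit).
#' @return An object of class `geotherm_params`.
#' @export
geotherm_params <- function(t_seafloor = 2, k_sediment = 1.0,
                            k_basement = 2.0, t_limit = 122) {
  stopifnot(k_sediment > 0, k_basement > 0, t_limit > t_seafloor)
  structure(list(t_seafloor = t_seafloor, k_sediment = k_sediment,
                 k_basement = k_basement, t_limit = t_limit),
            class = "geotherm_params")
}

#' Depth to the temperature-limit isotherm
#'
#' Depth below seafloor at which the conductive geotherm reaches
#' `t_limit` (122 C by default), given surface heat flow and sediment
#' thickness. Vectorized over `heatflow` and `sediment_thickness`.
#'
#' @param heatflow Heat flow (mW/m2), > 0.
#' @param sediment_thickness Sediment thickness (m), >= 0.
#' @param params A [geotherm_params()].
#' @return Isotherm depth (m below seafloor).
#' @export
#' @examples
#' isotherm_depth(100, 0, geotherm_params(k_sediment = 1, k_basement = 1))
#' # 1200 m: 1 * (122 - 2) / 0.1
isotherm_depth <- function(heatflow, sediment_thickness,
                           params = geotherm_params()) {
  stopifnot(inherits(params, "geotherm_params"))
  if (any(heatflow <= 0, na.rm = TRUE))
    abort("heat flow must be positive")
  q <- heatflow * 1e-3                       # mW/m2 -> W/m2
  dT <- params$t_limit - params$t_seafloor
  dT_sed_full <- q * sediment_thickness / params$k_sediment
  within_sed <- dT <= dT_sed_full
  depth <- ifelse(within_sed,
                  params$k_sediment * dT / q,
                  sediment_thickness +
                    params$k_basement * (dT - dT_sed_full) / q)
  depth
}

#' Habitable basement thickness
#'
#' Thickness of igneous basement cooler than the temperature limit:
#' `max(0, isotherm_depth - sediment_thickness)`.
#'
#' @param isotherm_depth Depth to the isotherm (m below seafloor).
#' @param sediment_thickness Sediment thickness (m).
#' @return Habitable basement thickness (m). Vectorized.
#' @export
habitable_basement_thickness <- function(isotherm_depth,
                                         sediment_thickness) {
  stopifnot(all(isotherm_depth >= 0, na.rm = TRUE),
            all(sediment_thickness >= 0, na.rm = TRUE))
  # first argument first: pmax takes attributes (e.g. dim) from it
  pmax(isotherm_depth - sediment_thickness, 0)
}

#' Basement porosity model
#'
#' Porosity `phi_upper` in the upper `z_break` m of basement, decreasing
#' linearly to zero at `z_zero` m into basement.
#'
#' @param phi_upper Upper-basement porosity (default 0.10).
#' @param z_break Depth into basement where the linear decrease starts
#'   (m, default 500).
#' @param z_zero Depth into basement where porosity reaches zero
#'   (m, default 1000).
#' @return An object of class `basement_porosity`.
#' @export
basement_porosity <- function(phi_upper = 0.10, z_break = 500,
                              z_zero = 1000) {
  stopifnot(phi_upper > 0, phi_upper < 1, z_break < z_zero, z_break >= 0)
  structure(list(phi_upper = phi_upper, z_break = z_break,
                 z_zero = z_zero),
            class = "basement_porosity")
}

#' Pore-volume column of habitable basement
#'
#' Integral of the basement porosity profile over the habitable thickness:
#' pore volume per unit seafloor area, in meters. Under the default model
#' a fully habitable column integrates to
#' `0.10 * 500 + 0.05 * 500 = 75 m`, the maximum attainable.
#'
#' @param habitable_thickness Habitable basement thickness (m), >= 0.
#'   Vectorized.
#' @param model A [basement_porosity()].
#' @return Pore column (m).
#' @export
basement_pore_column <- function(habitable_thickness,
                                 model = basement_porosity()) {
  stopifnot(inherits(model, "basement_porosity"),
            all(habitable_thickness >= 0, na.rm = TRUE))
  h <- pmin(habitable_thickness, model$z_zero)
  upper <- pmin(h, model$z_break) * model$phi_upper
  # linear segment: phi(z) = phi_upper * (z_zero - z)/(z_zero - z_break)
  hz <- pmax(h - model$z_break, 0)
  span <- model$z_zero - model$z_break
  lower <- model$phi_upper * (hz - hz^2 / (2 * span))
  upper + lower
}

#' Depth-averaged sedimentation rate
#'
#' `thickness / basement_age`, the long-term mean rate used by the
#' zonation classifier.
#'
#' @param thickness Sediment thickness (m).
#' @param basement_age Basement age (Ma), > 0.
#' @return Rate in m/Myr. Vectorized.
#' @export
mean_sedimentation_rate <- function(thickness, basement_age) {
  if (any(basement_age <= 0, na.rm = TRUE))
    abort("basement age must be positive")
  thickness / basement_age
}

#' Redox-zonation thresholds
#'
#' Sediment-thickness and sedimentation-rate boundaries beyond which
#' dissolved SO4^2- (and, at the lower set, O2) is depleted within the
#' sediment column.
#'
#' @param o2_thickness_max,o2_rate_max O2-persistence bounds
#'   (default 150 m, 15 m/Myr).
#' @param so4_thickness_max,so4_rate_max SO4-persistence bounds
#'   (default 500 m, 35 m/Myr).
#' @return An object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(o2_thickness_max = 150, o2_rate_max = 15,
                            so4_thickness_max = 500, so4_rate_max = 35) {
  stopifnot(o2_thickness_max <= so4_thickness_max,
            o2_rate_max <= so4_rate_max)
  structure(list(o2_thickness_max = o2_thickness_max,
                 o2_rate_max = o2_rate_max,
                 so4_thickness_max = so4_thickness_max,
                 so4_rate_max = so4_rate_max),
            class = "zone_thresholds")
}

ZONE_LEVELS <- c("oxic_to_basement", "sulfate_to_basement",
                 "sulfate_depleted")

#' Classify seafloor cells into redox-penetration zones
#'
#' A cell is `sulfate_depleted` if thickness or sedimentation rate
#' strictly exceeds the SO4 bounds; otherwise `oxic_to_basement` if both
#' are within the O2 bounds; otherwise `sulfate_to_basement`. Comparisons
#' are strict ("exceeds"), so boundary cells stay in the less-reduced
#' category.
#'
#' @param thickness Sediment thickness (m). Vectorized.
#' @param sed_rate Depth-averaged sedimentation rate (m/Myr).
#' @param thresholds A [zone_thresholds()].
#' @return Factor with levels `oxic_to_basement`, `sulfate_to_basement`,
#'   `sulfate_depleted`.
#' @export
#' @examples
#' classify_zone(600, 10)  # sulfate_depleted
#' classify_zone(100, 10)  # oxic_to_basement
classify_zone <- function(thickness, sed_rate,
                          thresholds = zone_thresholds()) {
  stopifnot(inherits(thresholds, "zone_thresholds"),
            all(thickness >= 0, na.rm = TRUE),
            all(sed_rate >= 0, na.rm = TRUE))
  out <- ifelse(
    thickness > thresholds$so4_thickness_max |
      sed_rate > thresholds$so4_rate_max,
    "sulfate_depleted",
    ifelse(thickness <= thresholds$o2_thickness_max &
             sed_rate <= thresholds$o2_rate_max,
           "oxic_to_basement", "sulfate_to_basement"))
  factor(out, levels = ZONE_LEVELS)
}

#' Zone areas and seafloor coverage fractions
#'
#' Classifies every (unmasked) cell from its sediment thickness and
#' depth-averaged sedimentation rate, and sums spherical cell areas per
#' category. Fractions are over the ocean mask and partition to 1.
#'
#' @param thickness Sediment-thickness [geo_grid()] (m).
#' @param age Basement-age [geo_grid()] (Ma).
#' @param thresholds A [zone_thresholds()].
#' @param ocean_mask Optional [geo_grid()]; cells with 0/`NA` excluded.
#' @return A data.frame with columns `zone`, `area_km2`, `fraction`.
#' @export
zone_areas <- function(thickness, age, thresholds = zone_thresholds(),
                       ocean_mask = NULL) {
  stopifnot(inherits(thickness, "geo_grid"), inherits(age, "geo_grid"))
  stop_unless_conformable(thickness, age)
  if (!is.null(ocean_mask)) stop_unless_conformable(thickness, ocean_mask)
  rate <- mean_sedimentation_rate(thickness$values, age$values)
  zones <- classify_zone(as.vector(thickness$values), as.vector(rate),
                         thresholds)
  areas <- as.vector(cell_areas(thickness))
  keep <- !is.na(zones)
  if (!is.null(ocean_mask))
    keep <- keep & !is.na(ocean_mask$values) & ocean_mask$values != 0
  a <- tapply(areas[keep], zones[keep], sum, default = 0)
  a[is.na(a)] <- 0
  data.frame(zone = ZONE_LEVELS,
             area_km2 = as.numeric(a[ZONE_LEVELS]),
             fraction = as.numeric(a[ZONE_LEVELS]) / sum(a),
             row.names = NULL)
}

#' Habitable-volume summary for a set of grids
#'
#' End-to-end convenience: isotherm depth per cell, habitable basement
#' thickness, rock and pore volumes integrated over the (masked) grid.
#'
#' @param heatflow,thickness [geo_grid()]s of heat flow (mW/m2) and
#'   sediment thickness (m).
#' @param params A [geotherm_params()].
#' @param porosity A [basement_porosity()].
#' @param ocean_mask Optional mask grid.
#' @return A list: `isotherm_depth` grid (m), `habitable_thickness` grid
#'   (m), `rock_volume_km3`, `pore_volume_km3`.
#' @export
habitable_volume <- function(heatflow, thickness,
                             params = geotherm_params(),
                             porosity = basement_porosity(),
                             ocean_mask = NULL) {
  stopifnot(inherits(heatflow, "geo_grid"), inherits(thickness, "geo_grid"))
  stop_unless_conformable(heatflow, thickness)
  iso <- isotherm_depth(heatflow$values, thickness$values, params)
  hab <- habitable_basement_thickness(iso, thickness$values)
  pore <- basement_pore_column(hab, porosity)
  iso_g <- geo_grid(iso, heatflow$lat_edges, heatflow$lon_edges, "m")
  hab_g <- geo_grid(hab, heatflow$lat_edges, heatflow$lon_edges, "m")
  pore_g <- geo_grid(pore, heatflow$lat_edges, heatflow$lon_edges, "m")
  list(isotherm_depth = iso_g,
       habitable_thickness = hab_g,
       rock_volume_km3 = integrate_volume(hab_g, ocean_mask),
       pore_volume_km3 = integrate_volume(pore_g, ocean_mask))
}
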