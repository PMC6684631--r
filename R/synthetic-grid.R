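# Smooth random global grids (heat flow, sediment thickness, basement age)
# for exercising the geomap module without external compilations.
#
# Fields are Gaussian random fields built by circular FFT convolution of
# white noise with a Gaussian kernel of SD `smoothness` cells, normalized
# to unit marginal variance, then mapped into the requested range through
# the normal CDF. As smoothness grows past the domain size all cells
# become perfectly correlated and the field tends to a constant.

#' Specify synthetic global grids
#'
#' @param resolution_deg Grid resolution in degrees; must divide 180
#'   evenly (e.g. 1, 2.5 is invalid, 0.5, 5, 10 are valid).
#' @param heatflow_range Heat-flow range (mW/m2), default `c(40, 200)`.
#' @param thickness_range Sediment-thickness range (m), default
#'   `c(0, 2000)`.
#' @param age_range Basement-age range (Ma), default `c(1, 180)`; lower
#'   bound must be > 0 so that ages are positive everywhere.
#' @param smoothness Correlation length in grid cells (default 5).
#' @param seed Integer seed.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(resolution_deg = 5,
                      heatflow_range = c(40, 200),
                      thickness_range = c(0, 2000),
                      age_range = c(1, 180),
                      smoothness = 5, seed = 1L) {
  ncell <- 180 / resolution_deg
  if (abs(ncell - round(ncell)) > 1e-9)
    abort("resolution_deg must divide 180 evenly")
  chk <- function(r, name, strict_pos = FALSE) {
    if (length(r) != 2 || r[1] > r[2] || any(r < 0))
      abort(name, " must be a non-negative (lo, hi) pair")
    if (strict_pos && r[1] <= 0)
      abort(name, " lower bound must be > 0")
  }
  chk(heatflow_range, "heatflow_range")
  chk(thickness_range, "thickness_range")
  chk(age_range, "age_range", strict_pos = TRUE)
  stopifnot(smoothness > 0)
  structure(list(resolution_deg = resolution_deg,
                 heatflow_range = heatflow_range,
                 thickness_range = thickness_range,
                 age_range = age_range,
                 smoothness = smoothness, seed = seed),
            class = "grid_spec")
}

# standardized smooth field (unit marginal variance) on an nlat x nlon grid
smooth_field <- function(nlat, nlon, smoothness) {
  white <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  di <- c(0:(nlat %/% 2), -((nlat - nlat %/% 2 - 1):1))
  dj <- c(0:(nlon %/% 2), -((nlon - nlon %/% 2 - 1):1))
  kern <- exp(-outer(di^2, dj^2, `+`) / (2 * smoothness^2))
  # circular convolution via FFT; normalize to unit variance
  sm <- Re(stats::fft(stats::fft(white) * stats::fft(kern), inverse = TRUE)) /
    (nlat * nlon)
  sm / sqrt(sum(kern^2))
}

range_map <- function(field_std, rng) {
  if (rng[1] == rng[2]) {
    matrix(rng[1], nrow(field_std), ncol(field_std))
  } else {
    rng[1] + (rng[2] - rng[1]) * stats::pnorm(field_std)
  }
}

#' Generate co-registered synthetic global grids
#'
#' Three spatially smooth random fields (heat flow, sediment thickness,
#' basement age) on the same global grid, each independently drawn and
#' mapped into its stated range. Deterministic under the spec seed.
#'
#' @param spec A [grid_spec()].
#' @return A list of three [geo_grid()]s: `heatflow` (mW/m2),
#'   `thickness` (m), `age` (Ma).
#' @export
#' @examples
#' g <- generate_grids(grid_spec(resolution_deg = 10, seed = 2))
#' range(g$age$values)  # strictly positive
generate_grids <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  nlat <- as.integer(round(180 / spec$resolution_deg))
  nlon <- 2L * nlat
  with_seed(spec$seed, {
    hf <- range_map(smooth_field(nlat, nlon, spec$smoothness),
                    spec$heatflow_range)
    th <- range_map(smooth_field(nlat, nlon, spec$smoothness),
                    spec$thickness_range)
    ag <- range_map(smooth_field(nlat, nlon, spec$smoothness),
                    spec$age_range)
    list(heatflow = geo_grid(hf, units = "mW/m2"),
         thickness = geo_grid(th, units = "m"),
         age = geo_grid(ag, units = "Ma"))
  })
}
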