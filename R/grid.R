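# Regular lat/lon grid container with spherical cell areas and
# ESRI ASCII I/O.

EARTH_RADIUS_KM <- 6371

#' Create a regular lat/lon grid
#'
#' Cell-centered values on a regular geographic grid. Latitude edges run
#' south to north in [-90, 90]; longitude edges west to east with
#' longitudes in [-180, 180).
#'
#' @param values Matrix of cell values, `nlat` rows (south to north) by
#'   `nlon` columns (west to east).
#' @param lat_edges,lon_edges Monotone increasing cell-edge vectors of
#'   lengths `nlat + 1` and `nlon + 1`. Defaults: a global grid at the
#'   resolution implied by `values`.
#' @param units Unit string for the field.
#' @return An object of class `geo_grid`.
#' @export
geo_grid <- function(values, lat_edges = NULL, lon_edges = NULL,
                     units = "") {
  stopifnot(is.matrix(values))
  nlat <- nrow(values); nlon <- ncol(values)
  if (is.null(lat_edges)) lat_edges <- seq(-90, 90, length.out = nlat + 1)
  if (is.null(lon_edges)) lon_edges <- seq(-180, 180, length.out = nlon + 1)
  if (length(lat_edges) != nlat + 1 || length(lon_edges) != nlon + 1)
    abort("edge vectors must match the value matrix dimensions")
  if (any(diff(lat_edges) <= 0) || any(diff(lon_edges) <= 0))
    abort("grid edges must be strictly increasing")
  structure(list(lat_edges = lat_edges, lon_edges = lon_edges,
                 values = values, units = units),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d x %d cells, lat [%g, %g], lon [%g, %g] %s\n",
              nrow(x$values), ncol(x$values),
              min(x$lat_edges), max(x$lat_edges),
              min(x$lon_edges), max(x$lon_edges),
              if (nzchar(x$units)) paste0("(", x$units, ")") else ""))
  invisible(x)
}

grids_conformable <- function(a, b) {
  isTRUE(all.equal(a$lat_edges, b$lat_edges)) &&
    isTRUE(all.equal(a$lon_edges, b$lon_edges))
}

stop_unless_conformable <- function(...) {
  gs <- list(...)
  for (g in gs[-1]) if (!grids_conformable(gs[[1]], g))
    abort("grids are not co-registered")
}

#' Spherical cell areas of a grid
#'
#' Cell area on a spherical Earth (R = 6371 km):
#' `R^2 * dlambda * (sin(lat2) - sin(lat1))`. For a global grid the areas
#' sum to `4 pi R^2`.
#'
#' @param grid A [geo_grid()].
#' @return Matrix of cell areas (km2), conformable with `grid$values`.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "geo_grid"))
  lat <- grid$lat_edges * pi / 180
  lon <- grid$lon_edges * pi / 180
  band <- EARTH_RADIUS_KM^2 * diff(sin(lat))     # per unit radian longitude
  outer(band, diff(lon))
}

#' Integrate a per-area field to a volume
#'
#' `sum(cell_area * field)` over unmasked cells; a field in meters
#' integrates to km3 (the meter-to-km conversion is applied internally).
#'
#' @param per_area_field A [geo_grid()] whose values are per-area
#'   thicknesses in meters.
#' @param mask Optional [geo_grid()] of logicals/0-1; cells with mask 0 or
#'   `NA` are excluded.
#' @return Volume in km3.
#' @export
integrate_volume <- function(per_area_field, mask = NULL) {
  stopifnot(inherits(per_area_field, "geo_grid"))
  areas <- cell_areas(per_area_field)
  v <- per_area_field$values * 1e-3                # m -> km
  if (!is.null(mask)) {
    stop_unless_conformable(per_area_field, mask)
    keep <- !is.na(mask$values) & mask$values != 0
    v[!keep] <- 0
  }
  sum(areas * v, na.rm = TRUE)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Standard ESRI ASCII grid dialect (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header; rows north to south). Requires square
#' cells.
#'
#' @param grid A [geo_grid()] with uniform, equal lat/lon spacing.
#' @param path Output path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "geo_grid"))
  dlat <- diff(grid$lat_edges); dlon <- diff(grid$lon_edges)
  if (diff(range(c(dlat, dlon))) > 1e-9)
    abort("ESRI ASCII requires uniform square cells")
  cs <- dlat[1]
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    sprintf("xllcorner %.10g", grid$lon_edges[1]),
    sprintf("yllcorner %.10g", grid$lat_edges[1]),
    sprintf("cellsize %.10g", cs),
    sprintf("NODATA_value %g", nodata)
  ), con)
  # rows north -> south
  for (i in rev(seq_len(nrow(vals))))
    writeLines(paste(format(vals[i, ], digits = 17), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File written by [write_esri_ascii()] or any conforming
#'   ESRI ASCII grid.
#' @param units Unit string to attach.
#' @return A [geo_grid()].
#' @export
read_esri_ascii <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- matrix(scan(text = lines[i:length(lines)], quiet = TRUE),
                 nrow = nr, ncol = nc, byrow = TRUE)
  vals <- vals[rev(seq_len(nr)), , drop = FALSE]   # back to south -> north
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  geo_grid(vals,
           lat_edges = hdr$yllcorner + cs * 0:nr,
           lon_edges = hdr$xllcorner + cs * 0:nc,
           units = units)
}
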