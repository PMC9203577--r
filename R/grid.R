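#' Construct a regular latitude-longitude grid geometry
#'
#' Defines the spatial frame every gridded field in the package lives on: cell
#' center coordinates, spherical cell areas and a binary land mask. Latitude
#' centers must be strictly ascending; cell areas are computed from spherical
#' geometry (Earth radius 6,371,000 m) so that a cell's area is proportional to
#' the difference of sines of its edge latitudes, i.e. approximately
#' cos(latitude) for a regular grid.
#'
#' @param lat numeric vector of cell-center latitudes in degrees north,
#'   strictly ascending, regular spacing.
#' @param lon numeric vector of cell-center longitudes in degrees east,
#'   regular spacing.
#' @param land_mask logical matrix `length(lat) x length(lon)`; `TRUE` marks a
#'   land cell. Must contain at least one land cell.
#' @return An object of class `grid_geometry`: a list with `lat`, `lon`,
#'   `cell_area` (matrix, m^2) and `land_mask`.
#' @examples
#' g <- grid_geometry(lat = seq(-88, 88, by = 4), lon = seq(-178, 178, by = 4),
#'                    land_mask = matrix(TRUE, 45, 90))
#' sum(g$cell_area) / 5.1e14  # close to 1: areas tile the sphere
#' @export
grid_geometry <- function(lat, lon, land_mask) {
  if (length(lat) < 1L || length(lon) < 1L)
    stop("lat and lon must be non-empty")
  if (is.unsorted(lat, strictly = TRUE))
    stop("lat centers must be strictly ascending")
  if (!is.matrix(land_mask) || !is.logical(land_mask) ||
      nrow(land_mask) != length(lat) || ncol(land_mask) != length(lon))
    stop("land_mask must be a logical matrix of dim length(lat) x length(lon)")
  if (!any(land_mask))
    stop("land_mask must contain at least one land cell")
  area <- cell_areas(lat, lon)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 cell_area = area, land_mask = land_mask),
            class = "grid_geometry")
}

# Spherical cell areas, m^2. Edges are midpoints between centers (clipped to
# +/-90); area = R^2 * dlon * (sin(top) - sin(bottom)).
cell_areas <- function(lat, lon, radius = 6371000) {
  dlat <- if (length(lat) > 1L) diff(lat)[1] else 1
  dlon <- if (length(lon) > 1L) abs(diff(lon)[1]) else 1
  top <- pmin(lat + dlat / 2, 90) * pi / 180
  bot <- pmax(lat - dlat / 2, -90) * pi / 180
  band <- radius^2 * (dlon * pi / 180) * (sin(top) - sin(bot))
  matrix(band, nrow = length(lat), ncol = length(lon))
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells (%.1f deg), %d land cells\n",
              length(x$lat), length(x$lon),
              if (length(x$lat) > 1) diff(x$lat)[1] else NA_real_,
              sum(x$land_mask)))
  invisible(x)
}

#' Create a named region mask
#'
#' @param name character label for the region.
#' @param member_cells logical matrix on the geometry's grid; must be a subset
#'   of the land mask.
#' @param geometry a [grid_geometry()] the mask refers to.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(name, member_cells, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!identical(dim(member_cells), dim(geometry$land_mask)))
    stop("member_cells dimensions do not match the geometry")
  if (any(member_cells & !geometry$land_mask))
    stop(sprintf("region '%s' contains non-land cells", name))
  structure(list(name = name, member_cells = member_cells),
            class = "region_mask")
}

#' Latitudinal band masks: Northern Hemisphere, tropics, southern extra-tropics
#'
#' Splits the land mask into the three bands used throughout the analysis:
#' the northern extra-tropics (cell-center latitude strictly greater than the
#' band boundary, 25 degrees N by default), the tropics (within the boundary on
#' both sides, inclusive), and the southern extra-tropics (strictly south of
#' it). A cell is assigned by its center latitude; the three masks always
#' partition the land mask.
#'
#' @param geometry a [grid_geometry()].
#' @param boundary band boundary in degrees (default 25).
#' @return Named list of three `region_mask` objects: `NH`, `tropics`, `SH`.
#' @export
default_bands <- function(geometry, boundary = 25) {
  lat <- geometry$lat
  nlon <- length(geometry$lon)
  latm <- matrix(lat, nrow = length(lat), ncol = nlon)
  lm <- geometry$land_mask
  list(
    NH      = region_mask("NH",      lm & latm >  boundary, geometry),
    tropics = region_mask("tropics", lm & latm <= boundary & latm >= -boundary,
                          geometry),
    SH      = region_mask("SH",      lm & latm < -boundary, geometry)
  )
}

#' Check that a collection of region masks partitions the land mask
#'
#' @param masks list of `region_mask` objects.
#' @param geometry a [grid_geometry()].
#' @return `TRUE` invisibly if the masks are pairwise disjoint and their union
#'   equals the land mask; otherwise an error.
#' @export
assert_partition <- function(masks, geometry) {
  stopifnot(length(masks) >= 1L)
  acc <- matrix(0L, nrow(geometry$land_mask), ncol(geometry$land_mask))
  for (m in masks) acc <- acc + m$member_cells
  if (any(acc > 1L))
    stop("region masks overlap: not a partition")
  if (!identical(acc == 1L, unname(geometry$land_mask)))
    stop("region masks do not cover the land mask")
  invisible(TRUE)
}

#' Assemble a monthly field set
#'
#' Bundles co-registered monthly gridded fields on one geometry and one time
#' axis. NEE follows the atmospheric sign convention: positive values are a
#' net carbon release from land to the atmosphere.
#'
#' @param geometry a [grid_geometry()].
#' @param years integer vector of consecutive calendar years covered (whole
#'   years only, at least 3).
#' @param nee net ecosystem exchange flux density, kgC m^-2 month^-1, array
#'   `nlat x nlon x (12 * length(years))`.
#' @param tws terrestrial water storage anomaly, mm.
#' @param temp air temperature, degrees C.
#' @param precip precipitation, mm month^-1.
#' @param pet potential evapotranspiration, mm month^-1.
#' @return An object of class `monthly_fieldset`.
#' @export
monthly_fieldset <- function(geometry, years, nee, tws, temp, precip, pet) {
  stopifnot(inherits(geometry, "grid_geometry"))
  years <- as.integer(years)
  if (length(years) < 3L)
    stop("time span must cover at least 3 whole years")
  if (any(diff(years) != 1L))
    stop("years must be consecutive")
  nt <- 12L * length(years)
  dims <- c(length(geometry$lat), length(geometry$lon), nt)
  fields <- list(nee = nee, tws = tws, temp = temp, precip = precip, pet = pet)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!is.array(f) || !identical(dim(f), as.integer(dims)))
      stop(sprintf("field '%s' must be an array of dim %s", nm,
                   paste(dims, collapse = " x ")))
    if (anyNA(f))
      stop(sprintf("field '%s' contains missing values inside the span", nm))
  }
  structure(c(list(geometry = geometry, years = years), fields),
            class = "monthly_fieldset")
}

#' @export
print.monthly_fieldset <- function(x, ...) {
  cat(sprintf("monthly_fieldset: %d-%d (%d years), %d x %d grid, %d land cells\n",
              min(x$years), max(x$years), length(x$years),
              length(x$geometry$lat), length(x$geometry$lon),
              sum(x$geometry$land_mask)))
  invisible(x)
}

# month-of-year (1..12) and year index for each time step of a fieldset
time_index <- function(years) {
  list(month = rep(1:12, times = length(years)),
       year  = rep(years, each = 12L))
}
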