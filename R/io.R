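# NetCDF and CSV input/output. Files follow CF-style conventions: dimensions
# time/lat/lon, coordinate variables in degrees north/east, per-variable units
# attributes, and integer year/month variables along the time axis.

fieldset_units <- c(nee = "kgC m-2 month-1", tws = "mm", temp = "degC",
                    precip = "mm month-1", pet = "mm month-1")

#' Write a monthly fieldset to NetCDF
#'
#' @param fieldset a [monthly_fieldset()].
#' @param path output file path.
#' @param variable_map named character vector mapping internal field names
#'   (`nee`, `tws`, `temp`, `precip`, `pet`) to variable names in the file.
#' @return `path`, invisibly.
#' @export
write_fieldset <- function(fieldset, path,
                           variable_map = stats::setNames(names(fieldset_units),
                                                          names(fieldset_units))) {
  stopifnot(inherits(fieldset, "monthly_fieldset"))
  g <- fieldset$geometry
  nt <- 12L * length(fieldset$years)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dtim <- ncdf4::ncdim_def("time", "months", seq_len(nt), unlim = FALSE)
  prec <- "double"
  vars <- list(
    ncdf4::ncvar_def("year", "calendar year", dtim, prec = "integer"),
    ncdf4::ncvar_def("month", "calendar month", dtim, prec = "integer"),
    ncdf4::ncvar_def("land_mask", "1=land", list(dlon, dlat), prec = "integer"),
    ncdf4::ncvar_def("cell_area", "m2", list(dlon, dlat), prec = prec)
  )
  for (nm in names(fieldset_units))
    vars[[length(vars) + 1L]] <-
      ncdf4::ncvar_def(unname(variable_map[[nm]]), fieldset_units[[nm]],
                       list(dlon, dlat, dtim), prec = prec)
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ti <- time_index(fieldset$years)
  ncdf4::ncvar_put(nc, "year", ti$year)
  ncdf4::ncvar_put(nc, "month", ti$month)
  ncdf4::ncvar_put(nc, "land_mask", t(g$land_mask * 1L))
  ncdf4::ncvar_put(nc, "cell_area", t(g$cell_area))
  for (nm in names(fieldset_units))
    ncdf4::ncvar_put(nc, unname(variable_map[[nm]]),
                     aperm(fieldset[[nm]], c(2, 1, 3)))
  ncdf4::ncatt_put(nc, 0, "nee_sign_convention",
                   "positive = net carbon release from land to atmosphere")
  invisible(path)
}

#' Read a monthly fieldset from NetCDF
#'
#' Validates the file on the way in: every mapped variable must exist, the
#' latitude axis must be strictly monotone, and the year/month axis must cover
#' whole consecutive calendar years with no gaps. Latitudes stored descending
#' are flipped to the package's ascending convention.
#'
#' @param path NetCDF file path.
#' @param variable_map named character vector mapping internal field names to
#'   file variable names (default: identical names).
#' @return A [monthly_fieldset()].
#' @export
read_fieldset <- function(path,
                          variable_map = stats::setNames(names(fieldset_units),
                                                         names(fieldset_units))) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  have <- names(nc$var)
  for (nm in names(fieldset_units)) {
    if (!nm %in% names(variable_map))
      stop(sprintf("variable_map is missing an entry for '%s'", nm))
    if (!variable_map[[nm]] %in% have)
      stop(sprintf("file has no variable '%s' (mapped for '%s')",
                   variable_map[[nm]], nm))
  }
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  flip <- FALSE
  if (is.unsorted(lat, strictly = TRUE)) {
    if (is.unsorted(rev(lat), strictly = TRUE))
      stop("latitude axis is not monotone")
    lat <- rev(lat); flip <- TRUE
  }
  yr <- as.integer(ncdf4::ncvar_get(nc, "year"))
  mo <- as.integer(ncdf4::ncvar_get(nc, "month"))
  years <- unique(yr)
  if (length(yr) != 12L * length(years) ||
      !identical(mo, rep(1:12, times = length(years))) ||
      !identical(yr, rep(years, each = 12L)))
    stop("ragged time axis: need whole consecutive calendar years")
  lm <- if ("land_mask" %in% have) {
    t(ncdf4::ncvar_get(nc, "land_mask")) == 1L
  } else {
    matrix(TRUE, length(lat), length(lon))
  }
  if (flip) lm <- lm[rev(seq_along(lat)), , drop = FALSE]
  geom <- grid_geometry(lat, lon, lm)
  get_field <- function(nm) {
    a <- aperm(ncdf4::ncvar_get(nc, variable_map[[nm]], collapse_degen = FALSE),
               c(2, 1, 3))
    if (flip) a <- a[rev(seq_along(lat)), , , drop = FALSE]
    a
  }
  monthly_fieldset(geom, years,
                   nee = get_field("nee"), tws = get_field("tws"),
                   temp = get_field("temp"), precip = get_field("precip"),
                   pet = get_field("pet"))
}

#' Write a contribution decomposition to NetCDF
#'
#' Stores the per-cell per-calendar-month contribution fields together with
#' the global correlations they decompose (as global attributes), the
#' undefined-cell quality layer and the geometry.
#'
#' @param fit an `nee_decomposition` from [nee_decompose()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contribution_map <- function(fit, path) {
  stopifnot(inherits(fit, "nee_decomposition"))
  g <- fit$geometry
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dmon <- ncdf4::ncdim_def("month", "calendar month", 1:12)
  vars <- list(
    ncdf4::ncvar_def("C_T", "1", list(dlon, dlat, dmon), prec = "double"),
    ncdf4::ncvar_def("C_TWS", "1", list(dlon, dlat, dmon), prec = "double"),
    ncdf4::ncvar_def("undefined", "1=zero-variance cell-month",
                     list(dlon, dlat, dmon), prec = "integer"),
    ncdf4::ncvar_def("land_mask", "1=land", list(dlon, dlat), prec = "integer")
  )
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "C_T", aperm(fit$C_T, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, "C_TWS", aperm(fit$C_TWS, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, "undefined", aperm(fit$undefined * 1L, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, "land_mask", t(g$land_mask * 1L))
  ncdf4::ncatt_put(nc, 0, "r_T", fit$r_T, prec = "double")
  ncdf4::ncatt_put(nc, 0, "r_TWS", fit$r_TWS, prec = "double")
  ncdf4::ncatt_put(nc, 0, "partial_r_T", fit$partial_r_T, prec = "double")
  ncdf4::ncatt_put(nc, 0, "partial_r_TWS", fit$partial_r_TWS, prec = "double")
  ncdf4::ncatt_put(nc, 0, "n_years", fit$n_years, prec = "int")
  ncdf4::ncatt_put(nc, 0, "excluded_years",
                   paste(fit$excluded_years, collapse = ","))
  invisible(path)
}

#' Read a contribution decomposition from NetCDF
#'
#' @param path file written by [write_contribution_map()].
#' @return An `nee_decomposition` object (without the global annual series,
#'   which is not stored in the map file).
#' @export
read_contribution_map <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  lm <- t(ncdf4::ncvar_get(nc, "land_mask")) == 1L
  geom <- grid_geometry(lat, lon, lm)
  att <- function(nm) ncdf4::ncatt_get(nc, 0, nm)$value
  exy <- att("excluded_years")
  structure(list(
    r_T = att("r_T"), r_TWS = att("r_TWS"),
    partial_r_T = att("partial_r_T"), partial_r_TWS = att("partial_r_TWS"),
    n_years = as.integer(att("n_years")),
    C_T = aperm(ncdf4::ncvar_get(nc, "C_T", collapse_degen = FALSE), c(2, 1, 3)),
    C_TWS = aperm(ncdf4::ncvar_get(nc, "C_TWS", collapse_degen = FALSE), c(2, 1, 3)),
    undefined = aperm(ncdf4::ncvar_get(nc, "undefined",
                                       collapse_degen = FALSE), c(2, 1, 3)) == 1L,
    globals = NULL, geometry = geom,
    excluded_years = if (nzchar(exy))
      as.integer(strsplit(exy, ",")[[1]]) else integer(0)
  ), class = "nee_decomposition")
}

#' Read or write a monthly CO2 mole-fraction series as CSV
#'
#' Plain-text layout with columns `year`, `month`, `ppm`, one row per month.
#'
#' @param path CSV file path.
#' @return `read_co2`: a data.frame with columns `year`, `month`, `ppm`.
#' @export
read_co2 <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("year", "month", "ppm") %in% names(x)))
    stop("CO2 file must have columns year, month, ppm")
  x[, c("year", "month", "ppm")]
}

#' @rdname read_co2
#' @param co2 data.frame with columns `year`, `month`, `ppm`.
#' @export
write_co2 <- function(co2, path) {
  utils::write.csv(co2[, c("year", "month", "ppm")], path, row.names = FALSE)
  invisible(path)
}
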