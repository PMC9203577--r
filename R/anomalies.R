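#' Remove the long-term linear trend from a monthly series
#'
#' Fits an ordinary least squares line against the monthly time index and
#' returns the residuals. The result has zero mean and zero OLS slope over the
#' fitting span to floating-point tolerance.
#'
#' @param x numeric vector of monthly values, length >= 24.
#' @return Numeric vector of anomalies, same length as `x`.
#' @export
detrend_whole_series <- function(x) {
  if (length(x) < 24L) stop("need at least 24 monthly values")
  detrend_rows(matrix(x, nrow = 1L))[1L, ]
}

#' Detrend a monthly series separately for each calendar month
#'
#' Splits the series into 12 groups, one per calendar month (all Januaries,
#' all Februaries, ...), removes an OLS linear trend against year from each
#' group independently, and recombines into a monthly series. This is the
#' anomaly construction used for the seasonal sensitivity regressions, where
#' a month-dependent trend must not leak into the seasonal anomalies.
#'
#' @param x numeric vector of monthly values covering whole calendar years
#'   (length a multiple of 12, at least 3 years).
#' @return Numeric vector of anomalies, same length as `x`.
#' @export
detrend_by_month_group <- function(x) {
  n <- length(x)
  if (n %% 12L != 0L) stop("series must cover whole calendar years")
  ny <- n %/% 12L
  if (ny < 3L) stop("need at least 3 years")
  m <- matrix(x, nrow = 12L)            # [month, year]
  res <- detrend_rows(m)                # each row is one calendar month
  as.numeric(res)
}

# OLS-detrend each row of a matrix against column index; returns residuals.
detrend_rows <- function(y) {
  nt <- ncol(y)
  tt <- seq_len(nt)
  tc <- tt - mean(tt)
  sxx <- sum(tc^2)
  ybar <- rowMeans(y)
  slope <- (y %*% tc) / sxx
  y - ybar - slope %*% rbind(tc)
}

#' Convert NEE flux density to an extensive per-cell quantity
#'
#' Multiplies a flux-density field (kgC m^-2 month^-1) by cell area and
#' converts to PgC month^-1 (1 PgC = 1e12 kgC). Non-land cells are set to
#' zero so that spatial sums over the land mask equal sums over all cells.
#'
#' @param nee_density array `nlat x nlon x ntime` of flux densities.
#' @param geometry a [grid_geometry()].
#' @return Array of the same shape, PgC month^-1 per cell.
#' @export
to_extensive <- function(nee_density, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  d <- dim(nee_density)
  if (length(d) != 3L || d[1] != length(geometry$lat) || d[2] != length(geometry$lon))
    stop("nee_density does not match the geometry")
  w <- geometry$cell_area * 1e-12
  w[!geometry$land_mask] <- 0
  nee_density * as.vector(w)   # recycles over time slices
}

#' Build a detrended anomaly cube from a monthly field set
#'
#' Converts NEE to extensive units (PgC month^-1 per cell), then removes the
#' long-term linear trend from the per-cell monthly series of NEE, TWS and
#' temperature. Detrending always uses the full record; volcanic-year
#' exclusion is applied later, when series are aggregated and correlated.
#'
#' @param fieldset a [monthly_fieldset()].
#' @param mode `"whole"` for whole-series detrending (used for the global
#'   correlation decomposition) or `"monthly"` for per-calendar-month
#'   detrending (used for seasonal sensitivities).
#' @param excluded_years integer years to drop from downstream statistics
#'   (default the volcanically perturbed 1982, 1991, 1992; years absent from
#'   the record are ignored).
#' @return An object of class `anomaly_cube`: arrays `nee` (PgC month^-1),
#'   `tws` (mm), `temp` (degrees C) of dim `nlat x nlon x ntime`, plus
#'   `geometry`, `years`, `detrend_mode`, `excluded_years`.
#' @export
anomaly_cube <- function(fieldset, mode = c("whole", "monthly"),
                         excluded_years = c(1982L, 1991L, 1992L)) {
  stopifnot(inherits(fieldset, "monthly_fieldset"))
  mode <- match.arg(mode)
  g <- fieldset$geometry
  nt <- 12L * length(fieldset$years)
  ncell <- length(g$lat) * length(g$lon)

  detrend_field <- function(a) {
    y <- matrix(a, nrow = ncell, ncol = nt)
    out <- if (mode == "whole") {
      detrend_rows(y)
    } else {
      res <- y
      yi <- rep(seq_along(fieldset$years), each = 12L)
      for (m in 1:12) {
        idx <- seq(m, nt, by = 12L)
        res[, idx] <- detrend_rows(y[, idx, drop = FALSE])
      }
      res
    }
    array(out, dim = dim(a))
  }

  nee_ext <- to_extensive(fieldset$nee, g)
  structure(list(
    geometry = g,
    years = fieldset$years,
    detrend_mode = mode,
    excluded_years = as.integer(excluded_years),
    nee = detrend_field(nee_ext),
    tws = detrend_field(fieldset$tws),
    temp = detrend_field(fieldset$temp)
  ), class = "anomaly_cube")
}

retained_years <- function(cube) {
  setdiff(cube$years, cube$excluded_years)
}

#' Aggregate an anomaly cube to global annual series
#'
#' The global annual NEE anomaly X_G(y) is the plain sum of the extensive
#' per-cell monthly anomalies over all cells and the 12 months of year y
#' (PgC yr^-1). The global temperature and TWS series are area-weighted means
#' over the land mask of the annual (mean-of-monthly) anomalies, keeping
#' native units. Excluded years are dropped from all three series after
#' detrending.
#'
#' @param cube an [anomaly_cube()] built with `mode = "whole"`.
#' @return A data.frame of class `global_annual_series` with columns `year`,
#'   `X_G` (PgC yr^-1), `T_G` (degrees C), `TWS_G` (mm).
#' @export
aggregate_global <- function(cube) {
  stopifnot(inherits(cube, "anomaly_cube"))
  if (cube$detrend_mode != "whole")
    stop("global aggregation requires whole-series detrended anomalies")
  g <- cube$geometry
  ny <- length(cube$years)
  ncell <- length(g$lat) * length(g$lon)

  # X_G: sum over cells and months within each year
  neem <- matrix(cube$nee, nrow = ncell)
  yi <- rep(seq_len(ny), each = 12L)
  X_G <- as.numeric(rowsum(colSums(neem), yi))

  # area-weighted land means of annual anomalies
  w <- as.vector(g$cell_area * g$land_mask)
  w <- w / sum(w)
  land_mean <- function(a) {
    m <- matrix(a, nrow = ncell)
    monthly <- as.numeric(crossprod(m, w))          # weighted mean per month
    as.numeric(rowsum(monthly, yi)) / 12
  }
  T_G <- land_mean(cube$temp)
  TWS_G <- land_mean(cube$tws)

  keep <- !(cube$years %in% cube$excluded_years)
  if (sum(keep) < 3L) stop("fewer than 3 retained years")
  out <- data.frame(year = cube$years[keep], X_G = X_G[keep],
                    T_G = T_G[keep], TWS_G = TWS_G[keep])
  class(out) <- c("global_annual_series", "data.frame")
  out
}

#' Annual CO2 growth rate from a monthly mole-fraction series
#'
#' The growth rate of year y is the difference between the CO2 mole fraction
#' in January of year y+1 and January of year y, in ppm yr^-1. The CO2 growth
#' rate is the classical observational proxy for the interannual variability
#' of the global net land-atmosphere carbon flux.
#'
#' @param co2 data.frame with columns `year`, `month`, `ppm` (monthly series).
#' @return A data.frame with columns `year` and `cgr` (ppm yr^-1), one row per
#'   year that has a January in both y and y+1.
#' @export
compute_cgr <- function(co2) {
  stopifnot(all(c("year", "month", "ppm") %in% names(co2)))
  jan <- co2[co2$month == 1L, ]
  jan <- jan[order(jan$year), ]
  if (nrow(jan) < 2L) stop("need January values for at least 2 consecutive years")
  if (any(diff(jan$year) != 1L)) stop("missing January in the CO2 series")
  data.frame(year = jan$year[-nrow(jan)], cgr = diff(jan$ppm))
}
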