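#' Classify dry and wet season months from PET and precipitation
#'
#' A month is dry in a given cell when the climatological (long-term monthly
#' mean) potential evapotranspiration strictly exceeds climatological
#' precipitation; otherwise it is wet (ties count as wet). Cells whose year is
#' entirely dry or entirely wet carry no dry/wet contrast and are flagged
#' excluded, as are non-land cells.
#'
#' @param x a [monthly_fieldset()] (climatologies are computed internally), or
#'   an `nlat x nlon x 12` array of climatological monthly precipitation.
#' @param pet climatological monthly PET array (only when `x` is an array).
#' @param geometry a [grid_geometry()] (only when `x` is an array).
#' @return An object of class `season_mask`: logical array `dry`
#'   (`nlat x nlon x 12`), logical matrix `excluded`, integer matrix `n_dry`.
#' @export
classify_dry_wet <- function(x, pet = NULL, geometry = NULL) {
  if (inherits(x, "monthly_fieldset")) {
    geometry <- x$geometry
    clim <- function(a) {
      ncell <- prod(dim(a)[1:2])
      m <- matrix(a, nrow = ncell)
      mi <- rep(1:12, times = dim(a)[3] / 12)
      cl <- t(rowsum(t(m), mi)) / (dim(a)[3] / 12)
      array(cl, dim = c(dim(a)[1:2], 12L))
    }
    precip12 <- clim(x$precip)
    pet12 <- clim(x$pet)
  } else {
    precip12 <- x
    if (is.null(pet) || is.null(geometry))
      stop("with array input, both pet and geometry are required")
    pet12 <- pet
  }
  d12 <- c(dim(geometry$land_mask), 12L)
  if (!identical(dim(precip12), as.integer(d12)) ||
      !identical(dim(pet12), as.integer(d12)))
    stop("climatologies must be nlat x nlon x 12 arrays (12 months required)")
  dry <- pet12 > precip12               # strict: tie months are wet
  n_dry <- apply(dry, c(1, 2), sum)
  excluded <- !geometry$land_mask | n_dry == 0L | n_dry == 12L
  structure(list(dry = dry, excluded = excluded, n_dry = n_dry,
                 geometry = geometry),
            class = "season_mask")
}

#' Dry-season length in months per cell
#'
#' @param mask a [classify_dry_wet()] season mask.
#' @return Integer matrix of dry-month counts (0-12); excluded cells are `NA`.
#' @export
dry_season_length <- function(mask) {
  stopifnot(inherits(mask, "season_mask"))
  out <- mask$n_dry
  out[mask$excluded] <- NA_integer_
  out
}

#' Per-cell seasonal sensitivity of NEE to TWS and temperature
#'
#' For every land cell, the monthly series of extensive NEE, TWS and
#' temperature are detrended separately for each calendar month, the months of
#' the requested season are summed within each year, and the seasonal NEE
#' anomaly is regressed on the seasonal TWS and temperature anomalies by
#' multiple linear regression (intercept included; the anomalies are
#' near-zero-mean so the intercept is ~0):
#'
#' \deqn{\mathrm{NEE}_{i,s} = a^{TWS}_{i,s}\,\mathrm{TWS}_{i,s}
#'       + a^{T}_{i,s}\,T_{i,s} + \varepsilon}
#'
#' A positive \eqn{a^{TWS}} means wetter conditions coincide with more carbon
#' release; a positive \eqn{a^T} means warmer conditions coincide with more
#' release (less net uptake).
#'
#' @param fieldset a [monthly_fieldset()].
#' @param season integer vector of calendar months (e.g. `6:8` for JJA), or a
#'   [classify_dry_wet()] mask together with `which = "dry"` or `"wet"` for
#'   per-cell seasons.
#' @param which `"dry"` or `"wet"`, used when `season` is a season mask.
#' @param excluded_years years dropped after detrending (default none: the
#'   sensitivity analysis uses the full record unless told otherwise).
#' @return An object of class `nee_sensitivity`: matrices `a_tws`
#'   (PgC month^-1 mm^-1), `a_t` (PgC month^-1 degC^-1), standard errors
#'   `se_tws`, `se_t`, `resid_sd`, and logical `undefined` (collinear or
#'   zero-variance predictors). Non-land (and, for mask seasons, excluded)
#'   cells are `NA`.
#' @export
seasonal_sensitivity <- function(fieldset, season, which = c("dry", "wet"),
                                 excluded_years = integer(0)) {
  stopifnot(inherits(fieldset, "monthly_fieldset"))
  cube <- anomaly_cube(fieldset, mode = "monthly", excluded_years = excluded_years)
  g <- cube$geometry
  nlat <- length(g$lat); nlon <- length(g$lon); ncell <- nlat * nlon
  keep <- !(cube$years %in% cube$excluded_years)
  ny <- sum(keep)
  if (ny < 4L) stop("need at least 4 retained years")

  # month-set per cell
  if (inherits(season, "season_mask")) {
    which <- match.arg(which)
    msel <- if (which == "dry") season$dry else !season$dry
    msel <- msel & !as.vector(season$excluded)
    season_label <- which
  } else {
    season <- as.integer(season)
    if (!length(season) || any(season < 1L | season > 12L))
      stop("season months must be in 1..12")
    msel <- array(FALSE, dim = c(nlat, nlon, 12L))
    msel[, , season] <- TRUE
    season_label <- paste(month.abb[season], collapse = "-")
  }

  # seasonal sums per cell per retained year: [ncell, ny]
  season_sum <- function(a) {
    x <- array(matrix(a, nrow = ncell), dim = c(ncell, 12L, length(cube$years)))
    x <- x[, , keep, drop = FALSE]
    w <- matrix(msel, nrow = ncell)     # [ncell, 12]
    out <- matrix(0, ncell, ny)
    for (m in 1:12) out <- out + x[, m, ] * w[, m]
    out
  }
  ys_nee <- season_sum(cube$nee)
  ys_tws <- season_sum(cube$tws)
  ys_t   <- season_sum(cube$temp)

  cxx <- function(a, b) rowSums((a - rowMeans(a)) * (b - rowMeans(b)))
  S11 <- cxx(ys_tws, ys_tws); S22 <- cxx(ys_t, ys_t); S12 <- cxx(ys_tws, ys_t)
  S1y <- cxx(ys_tws, ys_nee); S2y <- cxx(ys_t, ys_nee); Syy <- cxx(ys_nee, ys_nee)

  det <- S11 * S22 - S12^2
  bad <- !as.vector(g$land_mask) | rowSums(matrix(msel, nrow = ncell)) == 0 |
    S11 <= 0 | S22 <= 0 | det <= 1e-10 * S11 * S22
  det[bad] <- NA
  a_tws <- (S22 * S1y - S12 * S2y) / det
  a_t   <- (S11 * S2y - S12 * S1y) / det
  rss <- pmax(Syy - a_tws * S1y - a_t * S2y, 0)
  sigma2 <- rss / (ny - 3L)
  se_tws <- sqrt(sigma2 * S22 / det)
  se_t   <- sqrt(sigma2 * S11 / det)

  as_mat <- function(v) { v[bad] <- NA; matrix(v, nlat, nlon) }
  structure(list(
    a_tws = as_mat(a_tws), a_t = as_mat(a_t),
    se_tws = as_mat(se_tws), se_t = as_mat(se_t),
    resid_sd = as_mat(sqrt(sigma2)),
    undefined = matrix(bad & as.vector(g$land_mask), nlat, nlon),
    season = season_label, n_years = ny, geometry = g,
    excluded_years = cube$excluded_years
  ), class = "nee_sensitivity")
}

#' @export
print.nee_sensitivity <- function(x, ...) {
  ok <- !is.na(x$a_tws)
  cat(sprintf("Seasonal NEE sensitivity (%s), %d years, %d cells fitted\n",
              x$season, x$n_years, sum(ok)))
  cat(sprintf("  a_TWS: median %+.3e PgC/month per mm\n",
              stats::median(x$a_tws[ok])))
  cat(sprintf("  a_T:   median %+.3e PgC/month per degC\n",
              stats::median(x$a_t[ok])))
  invisible(x)
}

#' @export
coef.nee_sensitivity <- function(object, ...) {
  list(a_tws = object$a_tws, a_t = object$a_t)
}

#' @export
plot.nee_sensitivity <- function(x, coefficient = c("a_t", "a_tws"), ...) {
  coefficient <- match.arg(coefficient)
  a <- x[[coefficient]]
  graphics::image(x$geometry$lon, x$geometry$lat, t(a),
                  xlab = "longitude", ylab = "latitude",
                  main = sprintf("%s (%s)", coefficient, x$season), ...)
  invisible(x)
}
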