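#' Decompose global NEE-climate correlations into cell-month contributions
#'
#' The central fitting function. Given co-registered monthly fields, it
#' (1) detrends the per-cell monthly series and converts NEE to extensive
#' units, (2) forms the global annual series: the NEE anomaly X_G (PgC yr^-1)
#' and the area-weighted land means T_G and TWS_G, (3) computes the Pearson
#' and partial correlations of X_G with TWS_G and T_G, and (4) splits each
#' global correlation into additive contributions from every grid cell and
#' calendar month using the additivity of covariances over the extensive NEE
#' anomalies:
#'
#' \deqn{C^{T}_{i,m} = \mathrm{corr}(x_{i,m}, T_G)\,\sigma_{x_{i,m}}/\sigma_{X_G}
#'   = \mathrm{cov}(x_{i,m}, T_G)/(\sigma_{T_G}\sigma_{X_G})}
#'
#' so that \eqn{\sum_{i,m} C^{T}_{i,m} = r_T} exactly. The TWS contributions
#' carry an extra minus sign, \eqn{C^{TWS}_{i,m} = -\mathrm{corr}(x_{i,m},
#' \mathrm{TWS}_G)\,\sigma_{x_{i,m}}/\sigma_{X_G}}, so that positive values of
#' either contribution mean that removing that cell-month's NEE variability
#' would shrink the absolute value of the corresponding global correlation
#' (the global r_TWS is negative: more water, more uptake, lower NEE).
#'
#' Sample (n-1) standard deviations are used throughout; the ratio in the
#' weight is convention-invariant only because both numerator and denominator
#' use the same convention. Cell-months whose anomaly series has zero variance
#' contribute exactly 0 and are flagged in the `undefined` quality layer.
#'
#' @param fieldset a [monthly_fieldset()].
#' @param excluded_years years dropped after detrending, before any
#'   correlation (default 1982, 1991, 1992, the volcanically perturbed years).
#' @return An object of class `nee_decomposition` with components `r_T`,
#'   `r_TWS`, `partial_r_T`, `partial_r_TWS`, `n_years`, contribution arrays
#'   `C_T` and `C_TWS` (`nlat x nlon x 12`), the `undefined` flag array, the
#'   `globals` annual series, `geometry` and `excluded_years`.
#' @seealso [aggregate_contributions()], [summary.nee_decomposition()]
#' @examples
#' fs <- simulate_fieldset(sim_config(n_years = 12, grid_deg = 15, seed = 1))$fieldset
#' fit <- nee_decompose(fs, excluded_years = integer(0))
#' fit
#' @export
nee_decompose <- function(fieldset, excluded_years = c(1982L, 1991L, 1992L)) {
  cube <- anomaly_cube(fieldset, mode = "whole", excluded_years = excluded_years)
  globals <- aggregate_global(cube)
  fit <- contribution_map(cube, globals)
  fit$call <- match.call()
  fit
}

#' Per-cell, per-month contributions to the global correlations
#'
#' Lower-level interface taking an already-built anomaly cube and its global
#' annual series; [nee_decompose()] is the one-call wrapper. See that help
#' page for the definition of the contributions.
#'
#' @param cube an [anomaly_cube()] with `mode = "whole"`.
#' @param globals the matching [aggregate_global()] series.
#' @return An object of class `nee_decomposition`.
#' @export
contribution_map <- function(cube, globals) {
  stopifnot(inherits(cube, "anomaly_cube"),
            inherits(globals, "global_annual_series"))
  keep_years <- retained_years(cube)
  if (!identical(as.integer(globals$year), as.integer(keep_years)))
    stop("cube and globals do not share the same retained years")
  ny <- length(keep_years)
  g <- cube$geometry
  nlat <- length(g$lat); nlon <- length(g$lon)
  ncell <- nlat * nlon

  sd_X <- stats::sd(globals$X_G)
  if (sd_X == 0) stop("global NEE anomaly has zero variance")
  sd_T <- stats::sd(globals$T_G)
  sd_W <- stats::sd(globals$TWS_G)

  # x[cell*month, year] for retained years
  keep <- cube$years %in% keep_years
  x <- array(matrix(cube$nee, nrow = ncell), dim = c(ncell, 12L, length(cube$years)))
  x <- x[, , keep, drop = FALSE]
  xm <- matrix(x, nrow = ncell * 12L, ncol = ny)

  cov_with <- function(v) {
    as.numeric((xm - rowMeans(xm)) %*% (v - mean(v))) / (ny - 1)
  }
  C_T <- array(cov_with(globals$T_G) / (sd_T * sd_X), dim = c(nlat, nlon, 12L))
  C_W <- array(-cov_with(globals$TWS_G) / (sd_W * sd_X), dim = c(nlat, nlon, 12L))

  sdx <- sqrt(pmax(rowSums((xm - rowMeans(xm))^2), 0) / (ny - 1))
  undefined <- array(sdx == 0, dim = c(nlat, nlon, 12L))

  structure(list(
    r_T = pearson_r(globals$X_G, globals$T_G),
    r_TWS = pearson_r(globals$X_G, globals$TWS_G),
    partial_r_T = partial_r(globals$X_G, globals$T_G, globals$TWS_G),
    partial_r_TWS = partial_r(globals$X_G, globals$TWS_G, globals$T_G),
    n_years = ny,
    C_T = C_T,
    C_TWS = C_W,
    undefined = undefined,
    globals = globals,
    geometry = g,
    excluded_years = cube$excluded_years
  ), class = "nee_decomposition")
}

#' @export
print.nee_decomposition <- function(x, ...) {
  cat("Decomposition of global NEE interannual variability\n")
  cat(sprintf("  years retained: %d (excluded: %s)\n", x$n_years,
              if (length(x$excluded_years)) paste(x$excluded_years, collapse = ", ")
              else "none"))
  cat(sprintf("  r_TWS = %+.3f   (partial %+.3f)\n", x$r_TWS, x$partial_r_TWS))
  cat(sprintf("  r_T   = %+.3f   (partial %+.3f)\n", x$r_T, x$partial_r_T))
  cat(sprintf("  additivity residual: sum(C_T) - r_T = %.2e, sum(C_TWS) + r_TWS = %.2e\n",
              sum(x$C_T) - x$r_T, sum(x$C_TWS) + x$r_TWS))
  invisible(x)
}

#' Northern-hemisphere season month sets
#'
#' Boreal spring (MAM), summer (JJA), autumn (SON) and winter (DJF). Winter is
#' taken within the calendar year (January, February and December of the same
#' year) so that the four season sums add up exactly to the annual sum; the
#' bookkeeping convention is what makes the correlation decomposition close.
#'
#' @return Named list of integer month vectors.
#' @export
nh_seasons <- function() {
  list(MAM = 3:5, JJA = 6:8, SON = 9:11, DJF = c(12L, 1:2))
}

#' Aggregate cell-month contributions over regions and seasons
#'
#' Sums the per-cell per-month contributions over each region x season block
#' and reports them alongside fractional shares of the global correlations,
#' defined relative to |r|; negative contributions yield negative shares.
#' With the default regions (latitudinal bands) and the `annual` season the
#' rows add up to the global `(r_T, -r_TWS)` pair, i.e. shares of 100%.
#'
#' @param fit an `nee_decomposition` (from [nee_decompose()]).
#' @param regions list of [region_mask()]s (default the three latitudinal
#'   bands from [default_bands()]).
#' @param seasons named list of integer month vectors (default `annual` plus
#'   the four boreal seasons from [nh_seasons()]).
#' @return data.frame with columns `region`, `season`, `C_TWS`, `C_T`,
#'   `share_TWS`, `share_T` (shares as fractions of |r|).
#' @export
aggregate_contributions <- function(fit, regions = NULL,
                                    seasons = c(list(annual = 1:12), nh_seasons())) {
  stopifnot(inherits(fit, "nee_decomposition"))
  if (is.null(regions)) regions <- default_bands(fit$geometry)
  if (is.null(names(seasons)) || any(names(seasons) == ""))
    stop("seasons must be a named list of month vectors")
  rows <- list()
  for (rg in regions) {
    if (!sum(rg$member_cells))
      warning(sprintf("region '%s' is empty", rg$name))
    for (sn in names(seasons)) {
      months <- seasons[[sn]]
      cT <- sum(fit$C_T[, , months][rep(rg$member_cells, length(months))])
      cW <- sum(fit$C_TWS[, , months][rep(rg$member_cells, length(months))])
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg$name, season = sn, C_TWS = cW, C_T = cT,
        share_TWS = cW / abs(fit$r_TWS), share_T = cT / abs(fit$r_T))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate tropical contributions over per-cell dry and wet seasons
#'
#' Unlike the fixed boreal seasons, the dry and wet seasons are defined per
#' cell from the climatological PET-precipitation balance. Contributions are
#' summed over each cell's own dry (or wet) months; cells flagged as excluded
#' (all-dry or all-wet year) are skipped.
#'
#' @param fit an `nee_decomposition`.
#' @param season_mask a [classify_dry_wet()] mask.
#' @param regions list of [region_mask()]s (default: the tropics band).
#' @return data.frame with columns `region`, `season` ("dry"/"wet"), `C_TWS`,
#'   `C_T`, `share_TWS`, `share_T`.
#' @export
aggregate_dry_wet <- function(fit, season_mask, regions = NULL) {
  stopifnot(inherits(fit, "nee_decomposition"), inherits(season_mask, "season_mask"))
  if (is.null(regions)) regions <- default_bands(fit$geometry)["tropics"]
  rows <- list()
  for (rg in regions) {
    use <- rg$member_cells & !season_mask$excluded
    for (sn in c("dry", "wet")) {
      sel <- if (sn == "dry") season_mask$dry else !season_mask$dry
      sel <- sel & as.vector(use)   # [nlat, nlon, 12] & cell mask recycled
      cT <- sum(fit$C_T[sel])
      cW <- sum(fit$C_TWS[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg$name, season = sn, C_TWS = cW, C_T = cT,
        share_TWS = cW / abs(fit$r_TWS), share_T = cT / abs(fit$r_T))
    }
  }
  do.call(rbind, rows)
}

#' @export
summary.nee_decomposition <- function(object, ...) {
  tab <- aggregate_contributions(object)
  structure(list(fit = object, table = tab), class = "summary.nee_decomposition")
}

#' @export
print.summary.nee_decomposition <- function(x, ...) {
  print(x$fit)
  cat("\nRegion x season contributions:\n")
  tab <- x$table
  tab[, 3:6] <- round(tab[, 3:6], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.nee_decomposition <- function(x, driver = c("TWS", "T"), ...) {
  driver <- match.arg(driver)
  a <- if (driver == "TWS") x$C_TWS else x$C_T
  annual <- apply(a, c(1, 2), sum)
  annual[!x$geometry$land_mask] <- NA
  graphics::image(x$geometry$lon, x$geometry$lat, t(annual),
                  xlab = "longitude", ylab = "latitude",
                  main = sprintf("annual C^%s per cell", driver), ...)
  invisible(x)
}

#' Zero out NEE variability inside a region
#'
#' Utility for counterfactual checks: replaces the NEE series of every cell in
#' the region by its own long-term linear trend (so the region keeps its mean
#' and trend but loses all interannual variability). Re-running
#' [nee_decompose()] on the result shows how the global correlations move when
#' the region's variability is removed.
#'
#' @param fieldset a [monthly_fieldset()].
#' @param region a [region_mask()].
#' @return A modified `monthly_fieldset`.
#' @export
remove_region_nee <- function(fieldset, region) {
  stopifnot(inherits(fieldset, "monthly_fieldset"), inherits(region, "region_mask"))
  nt <- dim(fieldset$nee)[3]
  ncell <- prod(dim(fieldset$nee)[1:2])
  m <- matrix(fieldset$nee, nrow = ncell)
  idx <- which(as.vector(region$member_cells))
  if (length(idx)) {
    trend <- m[idx, , drop = FALSE] - detrend_rows(m[idx, , drop = FALSE])
    m[idx, ] <- trend
  }
  fieldset$nee <- array(m, dim = dim(fieldset$nee))
  fieldset
}

#' Sign agreement of aggregated contributions across datasets
#'
#' Given decompositions of the same grid from several input datasets (e.g. an
#' ensemble of flux products), reports for every region x season aggregate
#' whether all datasets agree on the sign of the contribution, and whether at
#' least `k` of the `n` datasets agree in sign with the ensemble mean (the
#' rule used for large model ensembles, e.g. more than 10 of 14).
#'
#' @param fits list of >= 2 `nee_decomposition` objects on one grid.
#' @param regions,seasons passed to [aggregate_contributions()].
#' @param k minimum number of datasets whose sign must match the ensemble-mean
#'   sign (default `ceiling(n/2)`).
#' @return data.frame with columns `region`, `season`, `driver`, `mean`,
#'   `all_same_sign`, `n_agree_mean`, `k_rule`.
#' @export
sign_consistency <- function(fits, regions = NULL,
                             seasons = c(list(annual = 1:12), nh_seasons()),
                             k = NULL) {
  if (length(fits) < 2L) stop("need at least 2 decompositions")
  geoms <- lapply(fits, function(f) dim(f$C_T))
  if (!all(vapply(geoms, identical, logical(1), geoms[[1]])))
    stop("decompositions are not on the same grid")
  n <- length(fits)
  if (is.null(k)) k <- ceiling(n / 2)
  tabs <- lapply(fits, aggregate_contributions, regions = regions, seasons = seasons)
  base <- tabs[[1]][, c("region", "season")]
  out <- list()
  for (driver in c("TWS", "T")) {
    col <- paste0("C_", driver)
    vals <- sapply(tabs, function(tt) tt[[col]])   # [aggregate, dataset]
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    mu <- rowMeans(vals)
    all_same <- apply(vals, 1L, function(v) all(v > 0) || all(v < 0))
    n_agree <- rowSums(sign(vals) == sign(mu))
    out[[driver]] <- data.frame(base, driver = driver, mean = mu,
                                all_same_sign = all_same,
                                n_agree_mean = n_agree,
                                k_rule = n_agree > k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
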