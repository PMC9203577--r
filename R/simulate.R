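# Seeded synthetic gridded fields with planted covariance structure.
#
# The generator does not aim at physical realism; it plants exactly the
# statistical structure the analysis assumes: latent global climate modes
# driving co-varying temperature and water-storage anomalies, region- and
# month-dependent NEE sensitivities, linear trends, seasonal cycles, white
# noise and optional volcanic-year pulses.

# deterministic per-component seed derived from one root seed
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 16807 + h * 2654435) %% 2147483629)
}

#' Configuration for the synthetic fieldset generator
#'
#' Defaults describe the reference study conditions: a 1979-2016 monthly
#' record (38 years) on a 4-degree grid, two AR(1) latent annual climate
#' modes (a hydrological and a thermal one, with cross-loadings so droughts
#' and heat co-occur), water-dominated tropical NEE with a negative TWS
#' sensitivity, a partially compensating spring/summer temperature sensitivity
#' in the northern extra-tropics, weak linear trends, and volcanic uptake
#' pulses in 1982, 1991 and 1992.
#'
#' @param seed integer root seed; all randomness flows from it through named
#'   per-component substreams.
#' @param start_year,n_years time span (whole calendar years, `n_years >= 3`).
#' @param grid_deg grid spacing in degrees (default 4).
#' @param land_frac fraction of cells drawn as land (default 0.35).
#' @param modes list of latent annual modes, each `list(sd=, ar1=)`; mode 1 is
#'   hydrological, mode 2 thermal.
#' @param t_loadings,tws_loadings loadings of temperature (degC) and TWS (mm)
#'   anomalies on the latent modes, uniform over land.
#' @param sens list of region specs `list(name=, lat_range=c(lo,hi), a_tws=,
#'   a_t=)` with 12-vectors (or scalars) of planted sensitivities in
#'   PgC month^-1 per mm / per degC per cell. `NULL` uses [default_sens()].
#' @param nee_resid `list(sd=, ar1=)`: an AR(1) annual NEE-only latent mode,
#'   independent of the climate modes, representing globally coherent NEE
#'   variability not driven by TWS or temperature (fire, radiation, ...). Its
#'   `sd` is the global annual standard deviation in PgC yr^-1, spread evenly
#'   over land cell-months; it keeps the global correlations away from +/-1
#'   without biasing contribution shares.
#' @param noise_sd named list: `t` (degC), `tws` (mm), `nee` (PgC month^-1 per
#'   cell) white-noise standard deviations.
#' @param trends named list of linear trends per year: `t` (degC yr^-1), `tws`
#'   (mm yr^-1), `nee` (PgC month^-1 yr^-1 per cell).
#' @param volcanic_years years receiving an additive uptake pulse;
#'   `volcanic_pulse` its size (PgC month^-1 per cell, negative = uptake).
#' @param dry_months_tropics calendar months whose climatological PET exceeds
#'   precipitation in tropical cells (extra-tropical cells are kept all-wet,
#'   so the dry/wet analysis excludes them).
#' @param mode_interp `"linear"` expands annual modes to months by linear
#'   interpolation between mid-year knots; `"step"` holds them constant within
#'   the year (used by scenarios that need exact within-year symmetry).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       start_year = 1979L, n_years = 38L,
                       grid_deg = 4, land_frac = 0.35,
                       modes = list(list(sd = 1, ar1 = 0.4),
                                    list(sd = 1, ar1 = 0.3)),
                       t_loadings = c(-0.3, 0.7),
                       tws_loadings = c(50, -15),
                       sens = NULL,
                       nee_resid = list(sd = 0.8, ar1 = 0.2),
                       noise_sd = list(t = 0.8, tws = 30, nee = 5e-5),
                       trends = list(t = 0.02, tws = -0.2, nee = -1e-6),
                       volcanic_years = c(1982L, 1991L, 1992L),
                       volcanic_pulse = -2e-4,
                       dry_months_tropics = 5:9,
                       mode_interp = c("linear", "step")) {
  mode_interp <- match.arg(mode_interp)
  if (n_years < 3L) stop("n_years must be at least 3")
  if (land_frac <= 0 || land_frac > 1) stop("land_frac must be in (0, 1]")
  for (m in modes) {
    if (m$sd < 0) stop("mode sd must be >= 0")
    if (abs(m$ar1) >= 1) stop("AR(1) coefficient must be in (-1, 1)")
  }
  if (length(t_loadings) != length(modes) || length(tws_loadings) != length(modes))
    stop("loadings must have one entry per mode")
  if (any(unlist(noise_sd) < 0)) stop("noise sd must be >= 0")
  if (nee_resid$sd < 0 || abs(nee_resid$ar1) >= 1)
    stop("nee_resid: sd must be >= 0 and AR(1) coefficient in (-1, 1)")
  if (is.null(sens)) sens <- default_sens()
  for (s in sens) {
    s$a_tws <- rep_len(s$a_tws, 12L); s$a_t <- rep_len(s$a_t, 12L)
  }
  structure(list(seed = as.integer(seed), start_year = as.integer(start_year),
                 n_years = as.integer(n_years), grid_deg = grid_deg,
                 land_frac = land_frac, modes = modes,
                 t_loadings = t_loadings, tws_loadings = tws_loadings,
                 sens = sens, nee_resid = nee_resid,
                 noise_sd = noise_sd, trends = trends,
                 volcanic_years = as.integer(volcanic_years),
                 volcanic_pulse = volcanic_pulse,
                 dry_months_tropics = as.integer(dry_months_tropics),
                 mode_interp = mode_interp),
            class = "sim_config")
}

#' Default planted sensitivities by latitudinal band
#'
#' Tropics: water-dominated NEE (negative TWS sensitivity: wetter years, more
#' uptake) with a small positive temperature sensitivity. Northern
#' extra-tropics: negative spring and positive summer temperature sensitivity
#' (partial seasonal compensation), small positive autumn/winter terms.
#' Southern extra-tropics: weak water control.
#'
#' @param nh_spring,nh_summer NH temperature sensitivities for MAM and JJA.
#' @param tropics_a_tws tropical TWS sensitivity (all months).
#' @return List of region sensitivity specs for [sim_config()].
#' @export
default_sens <- function(nh_spring = -4e-6, nh_summer = 8e-6,
                         tropics_a_tws = -5e-6) {
  a_t_nh <- numeric(12)
  a_t_nh[3:5] <- nh_spring
  a_t_nh[6:8] <- nh_summer
  a_t_nh[9:11] <- 2e-6
  a_t_nh[c(12, 1, 2)] <- 1e-6
  list(
    list(name = "NH", lat_range = c(25, 90), a_tws = rep(-1e-6, 12), a_t = a_t_nh),
    list(name = "tropics", lat_range = c(-25, 25),
         a_tws = rep(tropics_a_tws, 12), a_t = rep(4e-6, 12)),
    list(name = "SH", lat_range = c(-90, -25),
         a_tws = rep(-1e-6, 12), a_t = rep(1e-6, 12))
  )
}

#' Scenario with antisymmetric spring/summer temperature sensitivity
#'
#' Builds a [sim_config()] in which northern-hemisphere cells have a negative
#' spring (MAM) and positive summer (JJA) temperature sensitivity with
#' `|spring| = strength * |summer|`, zero elsewhere, and water-dominated
#' tropics. At `strength = 1` the planted annual NH temperature contribution
#' cancels by symmetry. The scenario is noiseless and trend-free by default,
#' and holds latent modes constant within each year so the spring/summer
#' antisymmetry is exact by construction.
#'
#' @param strength spring-to-summer magnitude ratio in `[0, 1]`.
#' @param summer_a_t summer (JJA) temperature sensitivity.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
make_compensation_scenario <- function(strength, summer_a_t = 8e-6, ...) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  a_t_nh <- numeric(12)
  a_t_nh[3:5] <- -strength * summer_a_t
  a_t_nh[6:8] <- summer_a_t
  sens <- list(
    list(name = "NH", lat_range = c(25, 90), a_tws = rep(0, 12), a_t = a_t_nh),
    list(name = "tropics", lat_range = c(-25, 25),
         a_tws = rep(-2e-6, 12), a_t = rep(0, 12)),
    list(name = "SH", lat_range = c(-90, -25),
         a_tws = rep(0, 12), a_t = rep(0, 12))
  )
  defaults <- list(sens = sens, mode_interp = "step",
                   nee_resid = list(sd = 0, ar1 = 0),
                   noise_sd = list(t = 0, tws = 0, nee = 0),
                   trends = list(t = 0, tws = 0, nee = 0),
                   volcanic_years = integer(0))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# expand per-region 12-vectors into per-cell-month maps [nlat, nlon, 12]
plant_sens_maps <- function(config, geometry) {
  nlat <- length(geometry$lat); nlon <- length(geometry$lon)
  a_tws <- array(0, c(nlat, nlon, 12L)); a_t <- array(0, c(nlat, nlon, 12L))
  for (s in config$sens) {
    inband <- geometry$lat >= s$lat_range[1] & geometry$lat <= s$lat_range[2]
    if (identical(s$name, "NH")) inband <- geometry$lat > s$lat_range[1]
    if (identical(s$name, "SH")) inband <- geometry$lat < s$lat_range[2]
    cells <- geometry$land_mask & inband
    atws12 <- rep_len(s$a_tws, 12L); at12 <- rep_len(s$a_t, 12L)
    for (m in 1:12) {
      sl_w <- a_tws[, , m]; sl_t <- a_t[, , m]
      sl_w[cells] <- atws12[m]; sl_t[cells] <- at12[m]
      a_tws[, , m] <- sl_w; a_t[, , m] <- sl_t
    }
  }
  list(a_tws = a_tws, a_t = a_t)
}

# stationary AR(1) annual series expanded to a monthly vector
latent_mode <- function(sd, ar1, n_years, interp, seed) {
  set.seed(seed)
  z <- numeric(n_years)
  z[1] <- stats::rnorm(1) * sd
  if (n_years > 1)
    for (y in 2:n_years)
      z[y] <- ar1 * z[y - 1] + stats::rnorm(1) * sd * sqrt(1 - ar1^2)
  monthly <- if (interp == "step") {
    rep(z, each = 12L)
  } else {
    knots <- (seq_len(n_years) - 1) * 12 + 6.5
    stats::approx(knots, z, xout = seq_len(12 * n_years), rule = 2)$y
  }
  list(annual = z, monthly = monthly)
}

#' Generate a synthetic monthly fieldset with known ground truth
#'
#' See [sim_config()] for the generative model. Output is deterministic given
#' the config's seed. The returned truth object carries the planted per-cell
#' sensitivity maps, the latent mode realizations, and the expected regional
#' contribution shares implied by the config (computed from the planted
#' sensitivities, the mode loadings and the stationary mode variances).
#'
#' @param config a [sim_config()].
#' @return List with elements `fieldset` (a [monthly_fieldset()]) and `truth`
#'   (class `sim_truth`: `a_tws`, `a_t` maps, `modes`, `expected_shares`).
#' @export
simulate_fieldset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$grid_deg
  lat <- seq(-90 + d / 2, 90 - d / 2, by = d)
  lon <- seq(-180 + d / 2, 180 - d / 2, by = d)
  nlat <- length(lat); nlon <- length(lon); ncell <- nlat * nlon
  ny <- config$n_years; nt <- 12L * ny
  years <- config$start_year + seq_len(ny) - 1L

  set.seed(sub_seed(config$seed, "land"))
  mask <- matrix(stats::runif(ncell) < config$land_frac, nlat, nlon)
  # every sensitivity band must hold at least one land cell
  for (s in config$sens) {
    inband <- lat > s$lat_range[1] & lat <= s$lat_range[2]
    if (any(inband) && !any(mask[inband, ]))
      mask[which(inband)[1], 1] <- TRUE
  }
  geom <- grid_geometry(lat, lon, mask)

  # latent modes
  K <- length(config$modes)
  modes_monthly <- matrix(0, nt, K)
  modes_annual <- matrix(0, ny, K)
  for (k in seq_len(K)) {
    mk <- latent_mode(config$modes[[k]]$sd, config$modes[[k]]$ar1, ny,
                      config$mode_interp, sub_seed(config$seed, paste0("mode", k)))
    modes_monthly[, k] <- mk$monthly
    modes_annual[, k] <- mk$annual
  }

  # anomaly fields [ncell, nt]
  rn <- function(name, sd) {
    if (sd == 0) return(matrix(0, ncell, nt))
    set.seed(sub_seed(config$seed, name))
    matrix(stats::rnorm(ncell * nt, sd = sd), ncell, nt)
  }
  t_anom <- matrix(1, ncell, 1) %*% t(modes_monthly %*% config$t_loadings) +
    rn("t_noise", config$noise_sd$t)
  w_anom <- matrix(1, ncell, 1) %*% t(modes_monthly %*% config$tws_loadings) +
    rn("tws_noise", config$noise_sd$tws)
  t_anom[!as.vector(mask), ] <- 0
  w_anom[!as.vector(mask), ] <- 0

  maps <- plant_sens_maps(config, geom)
  mo <- rep(1:12, times = ny)
  a_tws_cm <- matrix(maps$a_tws, nrow = ncell)[, mo]   # [ncell, nt]
  a_t_cm <- matrix(maps$a_t, nrow = ncell)[, mo]
  nee_ext <- a_tws_cm * w_anom + a_t_cm * t_anom + rn("nee_noise", config$noise_sd$nee)
  if (config$nee_resid$sd > 0) {
    resid_mode <- latent_mode(config$nee_resid$sd, config$nee_resid$ar1, ny,
                              config$mode_interp,
                              sub_seed(config$seed, "nee_resid"))
    nee_ext <- nee_ext +
      outer(as.numeric(mask) / (sum(mask) * 12), resid_mode$monthly)
  }
  nee_ext[!as.vector(mask), ] <- 0

  # trends (linear in time, slope per year) and volcanic pulses
  tfrac <- (seq_len(nt) - 1) / 12
  add_trend <- function(a, slope) a + outer(as.numeric(mask), slope * tfrac)
  t_anom <- add_trend(t_anom, config$trends$t)
  w_anom <- add_trend(w_anom, config$trends$tws)
  nee_ext <- add_trend(nee_ext, config$trends$nee)
  vol <- years %in% config$volcanic_years
  if (any(vol) && config$volcanic_pulse != 0) {
    sel <- rep(vol, each = 12L)
    nee_ext[, sel] <- nee_ext[, sel] + config$volcanic_pulse * as.numeric(mask)
  }

  # climatologies: temperature by latitude + hemispheric seasonal cycle;
  # precipitation/PET giving the configured tropical dry months
  latv <- rep(lat, times = nlon)
  seas <- sin((mo - 4) / 12 * 2 * pi)          # peaks boreal mid-summer
  t_clim <- outer(25 * cos(latv * pi / 180) - 8, rep(1, nt)) +
    outer(15 * sin(latv * pi / 180), seas)
  temp <- t_clim + t_anom
  nee_clim <- outer(-2e-4 * sin(latv * pi / 180), seas)   # NH uptake in summer
  nee_ext <- nee_ext + nee_clim * as.numeric(mask)

  tropic <- abs(latv) <= 25
  dry_cm <- matrix(0, ncell, 12L)
  dry_cm[tropic, config$dry_months_tropics] <- 1
  pet12 <- matrix(80, ncell, 12L)
  precip12 <- 120 - 80 * dry_cm                 # 40 in dry months, 120 in wet
  set.seed(sub_seed(config$seed, "precip_noise"))
  precip <- pmax(precip12[, mo] + matrix(stats::rnorm(ncell * nt, sd = 5), ncell, nt), 0)
  pet <- pmax(pet12[, mo] + 2 * outer(rep(1, ncell), seas), 0)
  precip[!as.vector(mask), ] <- 0
  pet[!as.vector(mask), ] <- 0

  # extensive PgC -> density kgC m^-2 month^-1
  dens <- nee_ext * 1e12 / as.vector(geom$cell_area)
  dens[!as.vector(mask), ] <- 0

  shp <- c(nlat, nlon, nt)
  fs <- monthly_fieldset(geom, years,
                         nee = array(dens, shp), tws = array(w_anom, shp),
                         temp = array(temp, shp), precip = array(precip, shp),
                         pet = array(pet, shp))
  truth <- structure(list(
    a_tws = maps$a_tws, a_t = maps$a_t,
    modes_annual = modes_annual, modes_monthly = modes_monthly,
    expected_shares = expected_shares(config, geom, maps),
    config = config
  ), class = "sim_truth")
  list(fieldset = fs, truth = truth)
}

# Population regional contribution shares implied by the planted structure.
# With uniform loadings L_T, L_W on modes of stationary variance v_k, the
# population covariances of the global drivers are ctt = sum(L_T^2 v),
# cww = sum(L_W^2 v), cwt = sum(L_T L_W v), and a cell-month's expected
# contribution is proportional to a_t*ctt + a_tws*cwt (for C^T) and
# -(a_tws*cww + a_t*cwt) (for C^TWS); noise adds zero in expectation.
expected_shares <- function(config, geometry, maps) {
  v <- vapply(config$modes, function(m) m$sd^2, numeric(1))
  ctt <- sum(config$t_loadings^2 * v)
  cww <- sum(config$tws_loadings^2 * v)
  cwt <- sum(config$t_loadings * config$tws_loadings * v)
  num_T <- maps$a_t * ctt + maps$a_tws * cwt
  num_W <- -(maps$a_tws * cww + maps$a_t * cwt)
  bands <- default_bands(geometry)
  share <- function(num) {
    tot <- sum(num)
    out <- vapply(bands, function(b) sum(num[rep(b$member_cells, 12L)]) / tot,
                  numeric(1))
    names(out) <- names(bands)
    out
  }
  list(share_T = share(num_T), share_TWS = share(num_W))
}

#' Generate a monthly atmospheric CO2 mole-fraction series
#'
#' The series is a baseline plus cumulative annual increments (the planted
#' growth rates), a within-year linear ramp, a seasonal cycle anchored to zero
#' in January, and optional white noise. With zero noise the January-to-January
#' growth rate of year y equals exactly the planted increment of year y.
#'
#' @param n_years number of years (>= 2).
#' @param seed integer seed for the increments and noise.
#' @param start_year first calendar year.
#' @param baseline January mole fraction of the first year, ppm.
#' @param increments annual growth rates, ppm yr^-1 (length `n_years`); by
#'   default drawn as `rnorm(n_years, mean_growth, growth_sd)`.
#' @param mean_growth,growth_sd distribution of the default increments.
#' @param seas_amp amplitude of the seasonal cycle, ppm.
#' @param noise_sd white-noise standard deviation, ppm.
#' @return List with `co2` (data.frame `year`, `month`, `ppm`) and
#'   `increments` (the planted growth rates).
#' @export
simulate_co2 <- function(n_years, seed = 1L, start_year = 1979L,
                         baseline = 339, increments = NULL,
                         mean_growth = 1.7, growth_sd = 0.5,
                         seas_amp = 3, noise_sd = 0) {
  if (n_years < 2L) stop("need at least 2 years")
  set.seed(sub_seed(seed, "co2"))
  if (is.null(increments))
    increments <- stats::rnorm(n_years, mean_growth, growth_sd)
  if (length(increments) != n_years) stop("need one increment per year")
  mo <- rep(1:12, times = n_years)
  yi <- rep(seq_len(n_years), each = 12L)
  cum_before <- c(0, cumsum(increments))[yi]
  seas <- seas_amp * (cos((mo - 1) / 12 * 2 * pi) - 1)   # 0 in January
  ppm <- baseline + cum_before + increments[yi] * (mo - 1) / 12 + seas
  if (noise_sd > 0) ppm <- ppm + stats::rnorm(length(ppm), sd = noise_sd)
  list(co2 = data.frame(year = start_year + yi - 1L, month = mo, ppm = ppm),
       increments = increments)
}
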