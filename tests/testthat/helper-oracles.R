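# Independent oracles, deliberately naive: explicit loops and closed forms,
# sharing no code with the implementation they check.

naive_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sab <- saa <- sbb <- 0
  for (i in seq_len(n)) {
    sab <- sab + (a[i] - ma) * (b[i] - mb)
    saa <- saa + (a[i] - ma)^2
    sbb <- sbb + (b[i] - mb)^2
  }
  sab / sqrt(saa * sbb)
}

closed_form_partial <- function(a, b, control) {
  rab <- naive_pearson(a, b)
  rac <- naive_pearson(a, control)
  rbc <- naive_pearson(b, control)
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

# OLS line fit by the 2x2 normal equations, solved by hand
hand_ols_line <- function(y) {
  n <- length(y)
  t <- seq_len(n)
  st <- sum(t); stt <- sum(t^2); sy <- sum(y); sty <- sum(t * y)
  det <- n * stt - st^2
  intercept <- (stt * sy - st * sty) / det
  slope <- (n * sty - st * sy) / det
  y - intercept - slope * t
}

# brute-force global annual NEE anomaly: triple loop over cells and months
naive_X_G <- function(nee_anom, years) {
  d <- dim(nee_anom)
  ny <- length(years)
  out <- numeric(ny)
  for (y in seq_len(ny)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (m in 1:12) {
      out[y] <- out[y] + nee_anom[i, j, (y - 1) * 12 + m]
    }
  }
  out
}

# small all-land fieldset from raw arrays, for hand-constructed cases
manual_fieldset <- function(lat, lon, years, nee_ext = NULL, tws, temp,
                            precip = NULL, pet = NULL) {
  nlat <- length(lat); nlon <- length(lon); nt <- 12L * length(years)
  geom <- grid_geometry(lat, lon, matrix(TRUE, nlat, nlon))
  if (is.null(precip)) precip <- array(100, c(nlat, nlon, nt))
  if (is.null(pet)) pet <- array(50, c(nlat, nlon, nt))
  dens <- nee_ext * 1e12 / as.vector(geom$cell_area)
  monthly_fieldset(geom, years, nee = dens, tws = tws, temp = temp,
                   precip = precip, pet = pet)
}

# quick toy simulation settings: coarse grid, short record, no volcanic years
toy_config <- function(seed, n_years = 15, grid_deg = 12, ...) {
  sim_config(seed = seed, n_years = n_years, grid_deg = grid_deg,
             volcanic_years = integer(0), ...)
}
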