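test_that("whole-series detrending removes constants and exact lines", {
  expect_equal(detrend_whole_series(rep(3.7, 48)), rep(0, 48))
  t <- 1:60
  expect_equal(detrend_whole_series(2 - 0.3 * t), rep(0, 60), tolerance = 1e-12)
  expect_error(detrend_whole_series(1:12), "24")
})

test_that("whole-series detrending matches a hand-solved normal-equation fit", {
  t <- 1:120
  y <- sin(2 * pi * t / 12) + 0.05 * t + 2
  expect_equal(detrend_whole_series(y), hand_ols_line(y), tolerance = 1e-12)
  # result has zero mean and zero OLS slope
  d <- detrend_whole_series(y)
  expect_lt(abs(mean(d)), 1e-12)
  expect_lt(abs(coef(lm(d ~ t))[2]), 1e-12)
})

test_that("detrending is idempotent", {
  set.seed(1)
  y <- rnorm(96) + 0.1 * (1:96)
  d1 <- detrend_whole_series(y)
  expect_equal(detrend_whole_series(d1), d1, tolerance = 1e-12)
  d2 <- detrend_by_month_group(y)
  expect_equal(detrend_by_month_group(d2), d2, tolerance = 1e-12)
})

test_that("per-month-group detrending removes month-dependent trends that
           whole-series detrending leaves behind", {
  ny <- 10
  yr <- rep(seq_len(ny), each = 12)
  mo <- rep(1:12, times = ny)
  y <- mo * yr              # slope differs by calendar month (1..12 per year)
  d_group <- detrend_by_month_group(y)
  expect_equal(d_group, rep(0, length(y)), tolerance = 1e-9)
  d_whole <- detrend_whole_series(y)
  # residual slope within at least one month group stays nonzero
  res_slopes <- sapply(1:12, function(m) {
    v <- d_whole[mo == m]
    coef(lm(v ~ seq_len(ny)))[2]
  })
  expect_gt(max(abs(res_slopes)), 0.1)
  # but per-group residual slopes from the grouped detrend are all ~0
  g_slopes <- sapply(1:12, function(m) {
    v <- d_group[mo == m]
    coef(lm(v ~ seq_len(ny)))[2]
  })
  expect_lt(max(abs(g_slopes)), 1e-9)
})

test_that("per-month-group detrend leaves zero mean and slope in white noise groups", {
  set.seed(42)
  y <- rnorm(12 * 8)
  d <- detrend_by_month_group(y)
  m <- matrix(d, nrow = 12)
  for (k in 1:12) {
    expect_lt(abs(mean(m[k, ])), 1e-12)
    expect_lt(abs(coef(lm(m[k, ] ~ seq_len(8)))[2]), 1e-12)
  }
})

test_that("extensive conversion is plain unit arithmetic over cell areas", {
  g <- grid_geometry(c(-45, 45), c(0, 90), matrix(TRUE, 2, 2))
  dens <- array(1, c(2, 2, 12))
  ext <- to_extensive(dens, g)
  expect_equal(ext[1, 1, 1], g$cell_area[1, 1] * 1e-12)
  expect_equal(to_extensive(array(0, c(2, 2, 12)), g), array(0, c(2, 2, 12)))
  # equal densities in two bands scale with the spherical area ratio
  expect_equal(ext[1, 1, 5] / ext[2, 1, 5],
               g$cell_area[1, 1] / g$cell_area[2, 1])
  # masked cells are zeroed
  g2 <- grid_geometry(c(-45, 45), c(0, 90),
                      matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_true(all(to_extensive(dens, g2)[2, 1, ] == 0))
})

test_that("global aggregation equals the brute-force triple sum", {
  set.seed(7)
  lat <- seq(-60, 60, 40); lon <- seq(-150, 150, 60)
  nlat <- length(lat); nlon <- length(lon); ny <- 6
  nee <- array(rnorm(nlat * nlon * 12 * ny), c(nlat, nlon, 12 * ny))
  fs <- manual_fieldset(lat, lon, 2001:(2000 + ny), nee_ext = nee,
                        tws = array(rnorm(nlat * nlon * 12 * ny), dim(nee)),
                        temp = array(rnorm(nlat * nlon * 12 * ny), dim(nee)))
  cube <- anomaly_cube(fs, "whole", excluded_years = integer(0))
  glob <- aggregate_global(cube)
  expect_equal(glob$X_G, naive_X_G(cube$nee, fs$years), tolerance = 1e-10)
})

test_that("spatially uniform temperature anomaly is its own area-weighted mean", {
  lat <- seq(-60, 60, 40); lon <- seq(-150, 150, 60)
  nlat <- length(lat); nlon <- length(lon); ny <- 5; nt <- 12 * ny
  set.seed(3)
  vals <- rnorm(nt)                       # same series in every cell
  temp <- array(rep(vals, each = nlat * nlon), c(nlat, nlon, nt))
  fs <- manual_fieldset(lat, lon, 2001:2005, nee_ext = array(rnorm(nlat*nlon*nt), c(nlat,nlon,nt)),
                        tws = temp, temp = temp)
  cube <- anomaly_cube(fs, "whole", excluded_years = integer(0))
  glob <- aggregate_global(cube)
  ref <- detrend_whole_series(vals)
  annual_ref <- colMeans(matrix(ref, nrow = 12))
  expect_equal(glob$T_G, annual_ref, tolerance = 1e-10)
  expect_equal(glob$TWS_G, annual_ref, tolerance = 1e-10)
})

test_that("opposite equal NEE anomalies cancel in the global sum", {
  lat <- c(-2, 2); lon <- c(0, 90)       # same |lat| so equal areas
  nt <- 12 * 4
  nee <- array(0, c(2, 2, nt))
  set.seed(9)
  s <- rnorm(nt)
  nee[1, 1, ] <- s
  nee[2, 1, ] <- -s
  z <- array(rnorm(2 * 2 * nt), c(2, 2, nt))
  fs <- manual_fieldset(lat, lon, 2001:2004, nee_ext = nee, tws = z, temp = z)
  cube <- anomaly_cube(fs, "whole", excluded_years = integer(0))
  expect_equal(aggregate_global(cube)$X_G, rep(0, 4), tolerance = 1e-12)
})

test_that("volcanic years are dropped after detrending, and the order matters", {
  sim <- simulate_fieldset(toy_config(11, n_years = 16))
  cube <- anomaly_cube(sim$fieldset, "whole", excluded_years = c(1982L))
  glob <- aggregate_global(cube)
  expect_false(1982 %in% glob$year)
  expect_equal(nrow(glob), 15)
  # excluding before detrending gives a different answer: the pinned order is
  # detrend on the full record, then drop
  fs2 <- sim$fieldset
  keep <- rep(fs2$years != 1982L, each = 12)
  sub <- lapply(c("nee", "tws", "temp", "precip", "pet"),
                function(nm) fs2[[nm]][, , keep, drop = FALSE])
  fs_cut <- monthly_fieldset(fs2$geometry, setdiff(fs2$years, 1982L)[1] + 0:14,
                             sub[[1]], sub[[2]], sub[[3]], sub[[4]], sub[[5]])
  glob_cut <- aggregate_global(anomaly_cube(fs_cut, "whole",
                                            excluded_years = integer(0)))
  expect_gt(max(abs(glob_cut$X_G - glob$X_G)), 1e-8)
})

test_that("CGR is the January-to-January first difference", {
  co2 <- data.frame(year = rep(2000:2004, each = 12), month = rep(1:12, 5),
                    ppm = 370)
  expect_equal(compute_cgr(co2)$cgr, rep(0, 4))
  co2$ppm <- 370 + 2 * (co2$year - 2000)      # +2 ppm every January
  expect_equal(compute_cgr(co2)$cgr, rep(2, 4))
  set.seed(5)
  co2$ppm <- rnorm(60)
  jan <- co2$ppm[co2$month == 1]
  expect_equal(compute_cgr(co2)$cgr,
               jan[2:5] - jan[1:4])            # direct indexing oracle
  expect_equal(compute_cgr(co2)$year, 2000:2003)
  expect_error(compute_cgr(co2[co2$month != 1, ]), "January")
})
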