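make_random_fit <- function(seed, n_years = 14, grid_deg = 20) {
  sim <- simulate_fieldset(toy_config(seed, n_years = n_years,
                                      grid_deg = grid_deg))
  nee_decompose(sim$fieldset, excluded_years = integer(0))
}

test_that("contributions sum exactly to the global correlations", {
  fit <- make_random_fit(1)
  expect_lt(abs(sum(fit$C_T) - fit$r_T), 1e-10 * max(1, abs(fit$r_T)))
  expect_lt(abs(sum(fit$C_TWS) + fit$r_TWS), 1e-10)
})

test_that("a single active cell-month carries the whole correlation", {
  lat <- c(-5, 5); lon <- c(0, 90)
  ny <- 12; nt <- 12 * ny
  set.seed(21)
  nee <- array(0, c(2, 2, nt))
  mar <- seq(3, nt, by = 12)
  # spike series orthogonal to {1, t} over the whole monthly axis, so the
  # long-term fit is the zero line and the sparsity pattern survives detrending
  v <- rnorm(ny)
  X <- cbind(1, mar)
  v <- as.numeric(v - X %*% qr.solve(X, v))
  nee[1, 1, mar] <- v                      # only cell (1,1), only March
  z <- function() array(rnorm(2 * 2 * nt), c(2, 2, nt))
  fs <- manual_fieldset(lat, lon, 2001:(2000 + ny), nee_ext = nee,
                        tws = z(), temp = z())
  fit <- nee_decompose(fs, excluded_years = integer(0))
  # weight sigma_x/sigma_XG collapses to 1: C_T equals r_T itself
  expect_equal(fit$C_T[1, 1, 3], fit$r_T, tolerance = 1e-12)
  expect_equal(sum(abs(fit$C_T)) - abs(fit$C_T[1, 1, 3]), 0)
  # all inactive cell-months are flagged undefined, the active one is not
  expect_false(fit$undefined[1, 1, 3])
  expect_true(all(fit$undefined[2, 2, ]))
})

test_that("zero-variance cell-months contribute exactly zero", {
  fit <- make_random_fit(2, grid_deg = 30)
  expect_true(all(fit$C_T[fit$undefined] == 0))
  expect_true(all(fit$C_TWS[fit$undefined] == 0))
  # ocean cells never contribute
  ocean <- !fit$geometry$land_mask
  expect_true(all(fit$C_T[array(ocean, dim(fit$C_T))] == 0))
})

test_that("contributions are invariant to positive rescaling of NEE and to
           additive shifts of the drivers", {
  sim <- simulate_fieldset(toy_config(3, n_years = 12, grid_deg = 20))
  fs <- sim$fieldset
  fit <- nee_decompose(fs, excluded_years = integer(0))
  fs2 <- fs
  fs2$nee <- fs$nee * 3.7
  fit2 <- nee_decompose(fs2, excluded_years = integer(0))
  expect_equal(fit2$C_T, fit$C_T, tolerance = 1e-12)
  expect_equal(fit2$C_TWS, fit$C_TWS, tolerance = 1e-12)
  fs3 <- fs
  fs3$temp <- fs$temp + 5
  fs3$tws <- fs$tws - 120
  fit3 <- nee_decompose(fs3, excluded_years = integer(0))
  expect_equal(fit3$C_T, fit$C_T, tolerance = 1e-12)
  expect_equal(fit3$r_TWS, fit$r_TWS, tolerance = 1e-12)
})

test_that("aggregation restates the identity: whole globe x all months = (r_T, -r_TWS)", {
  fit <- make_random_fit(4)
  globe <- region_mask("globe", fit$geometry$land_mask, fit$geometry)
  tab <- aggregate_contributions(fit, regions = list(globe),
                                 seasons = list(annual = 1:12))
  expect_equal(tab$C_T, fit$r_T, tolerance = 1e-10)
  expect_equal(tab$C_TWS, -fit$r_TWS, tolerance = 1e-10)
  # shares are +/-100% of |r|, signed like the contribution itself
  expect_equal(tab$share_T, sign(fit$r_T), tolerance = 1e-10)
  expect_equal(tab$share_TWS, -sign(fit$r_TWS), tolerance = 1e-10)
})

test_that("contributions are additive over complementary regions and seasons", {
  fit <- make_random_fit(5)
  bands <- default_bands(fit$geometry)
  tab <- aggregate_contributions(fit, regions = bands)
  ann <- tab[tab$season == "annual", ]
  expect_equal(sum(ann$C_T), fit$r_T, tolerance = 1e-10)
  expect_equal(sum(ann$C_TWS), -fit$r_TWS, tolerance = 1e-10)
  # four calendar seasons recompose each band's annual value exactly
  for (rg in unique(tab$region)) {
    sub <- tab[tab$region == rg, ]
    expect_equal(sum(sub$C_T[sub$season != "annual"]),
                 sub$C_T[sub$season == "annual"], tolerance = 1e-12)
  }
})

test_that("an empty region aggregates to zero with a warning", {
  fit <- make_random_fit(6)
  empty <- region_mask("empty", fit$geometry$land_mask & FALSE, fit$geometry)
  expect_warning(tab <- aggregate_contributions(fit, regions = list(empty),
                                                seasons = list(annual = 1:12)),
                 "empty")
  expect_equal(tab$C_T, 0)
})

test_that("removing a region's NEE variability moves |r| as its contribution predicts", {
  # Two-cell construction: the 'main' cell carries a noisy water-aligned NEE,
  # the small 'probe' cell a clean aligned (or anti-aligned) one. Removing a
  # probe with positive C_TWS must shrink |r_TWS|; a negative probe must
  # raise it. The property is first-order, so the probe is kept small.
  set.seed(31)
  lat <- c(-5, 5); lon <- c(0, 90)
  ny <- 30; nt <- 12 * ny
  W <- rep(rnorm(ny), each = 12)               # annual water anomaly, months equal
  temp <- array(rnorm(2 * 2 * nt), c(2, 2, nt))
  tws <- array(rep(W, each = 4) * 50, c(2, 2, nt))
  build <- function(probe_sign) {
    nee <- array(0, c(2, 2, nt))
    nee[1, 1, ] <- -5e-4 * W + rnorm(nt, sd = 2e-4)   # noisy aligned main cell
    nee[2, 1, ] <- probe_sign * 1e-4 * W              # clean probe cell
    manual_fieldset(lat, lon, 2001:(2000 + ny), nee_ext = nee,
                    tws = tws, temp = temp)
  }
  for (probe_sign in c(-1, +1)) {
    fs <- build(probe_sign)
    fit <- nee_decompose(fs, excluded_years = integer(0))
    geom <- fs$geometry
    probe <- region_mask("probe", matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2),
                         geom)
    contrib <- aggregate_contributions(fit, regions = list(probe),
                                       seasons = list(annual = 1:12))$C_TWS
    fit_wo <- nee_decompose(remove_region_nee(fs, probe),
                            excluded_years = integer(0))
    if (probe_sign < 0) {
      expect_gt(contrib, 0)                    # aligned probe contributes > 0
      expect_lt(abs(fit_wo$r_TWS), abs(fit$r_TWS))
    } else {
      expect_lt(contrib, 0)
      expect_gt(abs(fit_wo$r_TWS), abs(fit$r_TWS))
    }
  }
})

test_that("sign consistency flags full agreement, full disagreement and k-of-n rules", {
  fit <- make_random_fit(9)
  flip <- function(f) { f$C_T <- -f$C_T; f$C_TWS <- -f$C_TWS; f }
  same <- sign_consistency(list(fit, fit, fit))
  expect_true(all(same$all_same_sign))
  expect_true(all(same$n_agree_mean == 3))
  mixed <- sign_consistency(list(fit, flip(fit)))
  expect_false(any(mixed$all_same_sign))
  # planted 11-vs-3 split among 14 synthetic maps: consistent under >10 of 14
  ens <- c(replicate(11, fit, simplify = FALSE),
           replicate(3, flip(fit), simplify = FALSE))
  cons <- sign_consistency(ens, k = 10)
  expect_true(all(cons$n_agree_mean == 11))
  expect_true(all(cons$k_rule))
  # a 10-vs-4 split fails the strict "more than 10" rule
  ens2 <- c(replicate(10, fit, simplify = FALSE),
            replicate(4, flip(fit), simplify = FALSE))
  expect_false(any(sign_consistency(ens2, k = 10)$k_rule))
})

test_that("decomposition fails loudly when the global NEE anomaly is degenerate", {
  lat <- c(-5, 5); lon <- c(0, 90); nt <- 12 * 5
  z <- array(rnorm(2 * 2 * nt), c(2, 2, nt))
  fs <- manual_fieldset(lat, lon, 2001:2005, nee_ext = array(0, c(2, 2, nt)),
                        tws = z, temp = z)
  expect_error(nee_decompose(fs, excluded_years = integer(0)), "zero variance")
})
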