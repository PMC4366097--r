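test_that("normalization divides by M0 and masks unreliable voxels", {
  d <- c(4, 4, 2)
  off <- make_offset_grid(-4, 4, 13)
  m0 <- array(1000, dim = d)
  sat <- array(rep(500, prod(d) * 13), dim = c(d, 13))
  z <- normalize_zspectrum(sat, m0, off)
  expect_true(all(z$data == 0.5))
  expect_true(all(z$mask))
  # M = M0 everywhere -> Z identically 1
  z1 <- normalize_zspectrum(array(1000, dim = c(d, 13)), m0, off)
  expect_true(all(z1$data == 1))
  # an M0 of zero (or below the floor) masks the voxel out, not to zero
  m0b <- m0; m0b[1, 1, 1] <- 0; m0b[2, 1, 1] <- 10
  zb <- normalize_zspectrum(sat, m0b, off)
  expect_false(zb$mask[1, 1, 1])
  expect_false(zb$mask[2, 1, 1])
  expect_equal(sum(!zb$mask), 2)
  expect_error(normalize_zspectrum(sat, array(1, dim = c(4, 4, 3)), off),
               "spatial shape")
})

test_that("B0 estimation finds spline minima within stated tolerances", {
  # symmetric single Lorentzian centered at 0
  z0 <- one_voxel_zvol(list(pool_spec(0, 0.85, 3)))
  b0 <- estimate_b0(z0)
  expect_true(b0$valid[1, 1, 1])
  expect_lt(abs(b0$delta_ppm[1, 1, 1]), 0.01)
  # shifted multi-pool spectrum: recovered within 0.02 ppm of the shift
  pools <- default_pools(0.045)
  zs <- one_voxel_zvol(pools, b0_shift = 0.30)
  bs <- estimate_b0(zs)
  expect_lt(abs(bs$delta_ppm[1, 1, 1] - 0.30), 0.02)
  # and within 0.02 ppm of the independent analytic-minimum oracle
  expect_lt(abs(bs$delta_ppm[1, 1, 1] - analytic_zmin(pools, 0.30)), 0.02)
  # minimum beyond the search window: flagged invalid
  ze <- one_voxel_zvol(default_pools(0.08), b0_shift = 1.4)
  be <- estimate_b0(ze, search_halfwidth_ppm = 1)
  expect_false(be$valid[1, 1, 1])
  expect_error(estimate_b0(zspectrum_volume(
    array(1, dim = c(1, 1, 1, 3)), c(-1, 0, 1))), "4 offsets")
})

test_that("B0 correction recenters spectra and never extrapolates", {
  pools <- default_pools(0.08)
  zs <- one_voxel_zvol(pools, b0_shift = 0.30)
  b0 <- estimate_b0(zs)
  zc <- correct_b0(zs, b0)
  # corrected minimum back at 0 within 0.02 ppm
  mask_fin <- is.finite(zc$data[1, 1, 1, ])
  sf <- splinefun(zc$offsets_ppm[mask_fin], zc$data[1, 1, 1, mask_fin],
                  method = "natural")
  g <- seq(-1, 1, by = 0.001)
  expect_lt(abs(g[which.min(sf(g))]), 0.02)
  # positive shift pushes the +4 ppm node off the acquired range
  expect_true(is.na(zc$data[1, 1, 1, 13]))
  expect_true(all(is.finite(zc$data[1, 1, 1, 1:12])))
  # a zero B0 map leaves the data untouched
  b00 <- b0
  b00$delta_ppm[] <- 0
  zid <- correct_b0(zs, b00)
  expect_identical(zid$data, zs$data)
  # invalid-B0 voxels pass through unshifted but leave the mask
  b0i <- b0; b0i$valid[] <- FALSE
  zi <- correct_b0(zs, b0i)
  expect_identical(zi$data, zs$data)
  expect_false(any(zi$mask))
})

test_that("MTR asymmetry matches closed-form evaluation and clips only for display", {
  off <- make_offset_grid(-4, 4, 13)
  # symmetric spectrum: zero asymmetry
  zsym <- one_voxel_zvol(list(pool_spec(0, 0.85, 3)))
  msym <- compute_mtr_asym(zsym)
  expect_equal(msym$values_percent[1, 1, 1], 0, tolerance = 1e-10)
  # direct arithmetic: Z(-10/3)=0.60, Z(+10/3)=0.75 -> -15%
  # (the +/-10/3 readout points are the 2nd and 12th grid nodes)
  v <- rep(0.9, 13); v[2] <- 0.60; v[12] <- 0.75
  zman <- zspectrum_volume(array(v, dim = c(1, 1, 1, 13)), off)
  mman <- compute_mtr_asym(zman, readout_ppm = off[12])
  expect_equal(mman$values_percent[1, 1, 1], -15)
  # water + NOE pool against independent two-Lorentzian hand evaluation
  pools <- list(pool_spec(0, 0.85, 1.4), pool_spec(-3.3, 0.05, 3))
  zp <- one_voxel_zvol(pools)
  mp <- compute_mtr_asym(zp)
  lor <- function(x, c0, w) (w / 2)^2 / ((w / 2)^2 + (x - c0)^2)
  zval <- function(x) 1 - 0.85 * lor(x, 0, 1.4) - 0.05 * lor(x, -3.3, 3)
  expect_equal(mp$values_percent[1, 1, 1],
               100 * (zval(-10 / 3) - zval(10 / 3)), tolerance = 1e-9)
  expect_error(compute_mtr_asym(zp, readout_ppm = 5), "outside")
  # windowing clips for display only
  expect_equal(window_display(c(-12, 7, -3)), c(-10, 5, -3))
  expect_equal(window_display(mp)[1, 1, 1], mp$values_percent[1, 1, 1])
  expect_error(window_display(1, lo = 5, hi = -10), "below")
})

test_that("negating the offset axis flips every MTR_asym value exactly", {
  ph <- build_phantom(test_phantom_config(seed = 6))
  a <- simulate_acquisition(ph, acquisition_params(noise_sigma = 0.01),
                            seed = 3)
  z <- normalize_zspectrum(a)
  m1 <- compute_mtr_asym(z)
  flipped <- z$data[, , , rev(seq_along(z$offsets_ppm)), drop = FALSE]
  z2 <- zspectrum_volume(flipped, rev(-z$offsets_ppm), z$affine, z$mask)
  m2 <- compute_mtr_asym(z2)
  idx <- which(is.finite(m1$values_percent))
  expect_gt(length(idx), 100)
  expect_equal(m2$values_percent[idx], -m1$values_percent[idx],
               tolerance = 1e-10)
})

test_that("MTR_asym error against the analytic truth grows with noise", {
  ph <- build_phantom(test_phantom_config(seed = 8))
  truth <- mtr_asym_truth(ph)
  rmse <- vapply(c(0, 0.01, 0.04), function(sig) {
    a <- simulate_acquisition(ph, acquisition_params(noise_sigma = sig),
                              seed = 21)
    z <- normalize_zspectrum(a)
    zc <- correct_b0(z, estimate_b0(z))
    m <- compute_mtr_asym(zc)
    ok <- which(is.finite(m$values_percent) & zc$mask)
    ok <- ok[seq_len(min(200, length(ok)))]
    sqrt(mean((m$values_percent[ok] - truth[ok])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
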