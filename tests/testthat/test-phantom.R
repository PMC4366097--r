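test_that("phantom generation is deterministic per seed", {
  p1 <- build_phantom(test_phantom_config(seed = 11))
  p2 <- build_phantom(test_phantom_config(seed = 11))
  p3 <- build_phantom(test_phantom_config(seed = 12))
  expect_identical(p1$label_map, p2$label_map)
  expect_identical(p1$noe_amp_map, p2$noe_amp_map)
  expect_identical(p1$b0_field_ppm, p2$b0_field_ppm)
  expect_identical(p1$cellularity_map, p2$cellularity_map)
  expect_false(identical(p1$b0_field_ppm, p3$b0_field_ppm))
})

test_that("phantom contains every tissue class with the stated orderings", {
  ph <- build_phantom(test_phantom_config(seed = 2))
  lab <- ph$label_map
  for (v in tissue_labels()) expect_gt(sum(lab == v), 0)
  cls <- function(v) mean(ph$noe_amp_map[lab == v])
  # NOE amplitude decreases NAWM > edema > CE tumor > necrosis
  expect_true(cls(1) > cls(2) && cls(2) > cls(3) && cls(3) > cls(4))
  adc <- function(v) mean(ph$adc_map[lab == v])
  # ADC increases edema < CE tumor < necrosis
  expect_true(adc(2) < adc(3) && adc(3) < adc(4))
  # MTR_asym ground truth increases NAWM -> edema -> CE tumor -> necrosis
  mtr <- mtr_asym_truth(ph)
  mcls <- function(v) mean(mtr[lab == v])
  expect_true(mcls(1) < mcls(2) && mcls(2) < mcls(3) && mcls(3) < mcls(4))
  # acellular background and CSF, non-negative fields
  expect_true(all(ph$cellularity_map[lab == 0 | lab == 5] == 0))
  expect_true(all(ph$adc_map >= 0) && all(ph$cellularity_map >= 0))
  expect_lte(max(abs(ph$b0_field_ppm)), 0.3 + 1e-12)
})

test_that("an impossible contrast ordering is rejected", {
  tt <- tissue_contrast_table()
  tt$noe_amp[tt$tissue == "t2_edema"] <- 0.2  # above NAWM
  expect_error(build_phantom(test_phantom_config(tissue_table = tt)),
               "decrease")
  tt2 <- tissue_contrast_table()
  tt2$adc_mean[tt2$tissue == "necrosis"] <- 1000
  expect_error(build_phantom(test_phantom_config(tissue_table = tt2)),
               "increase")
})

test_that("copula coupling reproduces the configured rank correlations", {
  # cellularity vs NOE amplitude inside CE tumor, on the full-size phantom
  # so the class holds >= 1000 voxels
  for (rho in c(0, 0.8)) {
    ph <- build_phantom(phantom_config(seed = 3, rho_cell = rho))
    sel <- ph$label_map == 3L
    expect_gte(sum(sel), 1000)
    r <- spearman_rs(ph$cellularity_map[sel], ph$noe_amp_map[sel])$r
    tol <- if (rho == 0) 0.1 else 0.05
    expect_lt(abs(r - rho), tol)
  }
})

test_that("acquisition is noise-free exact and reproducible under noise", {
  ph <- build_phantom(test_phantom_config(seed = 4))
  acq0 <- acquisition_params(noise_sigma = 0)
  a <- simulate_acquisition(ph, acq0)
  # round trip: Z = M/M0 returns the model values to machine precision
  ztrue <- zspectrum_truth(ph, acq0$offsets_ppm)
  head_idx <- which(ph$label_map != 0L)
  for (k in c(1L, 7L, 13L)) {
    zk <- a$sat[, , , k] / a$m0
    expect_equal(zk[head_idx], ztrue[, , , k][head_idx], tolerance = 1e-12)
  }
  # all noise-free Z in (0, 1]
  expect_true(all(ztrue > 0 & ztrue <= 1))
  # with no pools at all the saturated volumes equal M0
  cfg0 <- test_phantom_config(seed = 4)
  cfg0$water_amp <- 0
  tt <- cfg0$tissue_table; tt$noe_amp <- c(4, 3, 2, 1, 0.5) * 1e-12
  cfg0$tissue_table <- tt
  ph0 <- build_phantom(cfg0)
  a0 <- simulate_acquisition(ph0, acq0)
  expect_equal(a0$sat[, , , 5], a0$m0, tolerance = 1e-9)
  # fixed seed reproduces the noisy stack bit for bit
  acqn <- acquisition_params(noise_sigma = 0.02)
  n1 <- simulate_acquisition(ph, acqn, seed = 9)
  n2 <- simulate_acquisition(ph, acqn, seed = 9)
  n3 <- simulate_acquisition(ph, acqn, seed = 10)
  expect_identical(n1$sat, n2$sat)
  expect_false(identical(n1$sat, n3$sat))
  # background sits near the noise floor, far below tissue signal
  expect_lt(mean(n1$m0[ph$label_map == 0L]), 0.05 * mean(n1$m0[head_idx]))
})

test_that("biopsy series samples the cellularity field along the line", {
  ph <- build_phantom(test_phantom_config(seed = 5))
  # all distances zero: every sample at the target
  tr0 <- trajectory_spec(c(30, 30, 10), c(2, 2, 0),
                         sample_distances_mm = rep(0, 3))
  s0 <- simulate_biopsy_set(ph, tr0, cell_noise_cv = 0)
  expect_equal(nrow(s0), 3)
  expect_true(all(s0$x_mm == 2 & s0$y_mm == 2 & s0$z_mm == 0))
  expect_equal(length(unique(s0$cell_density_per_mm3)), 1L)
  # noise-free sampling at a voxel center returns the map value exactly
  vox <- c(16L, 16L, 10L)
  w <- voxel_to_world(vox, ph$affine)
  tr1 <- trajectory_spec(w + c(0, 20, 0), w, sample_distances_mm = 0)
  s1 <- simulate_biopsy_set(ph, tr1, cell_noise_cv = 0)
  expect_equal(s1$cell_density_per_mm3,
               ph$cellularity_map[vox[1] + 1, vox[2] + 1, vox[3] + 1])
  # 12 equally spaced specimens: 12 rows, monotone distances, inside volume
  s12 <- simulate_biopsy_set(ph, default_trajectory(ph), seed = 2)
  expect_equal(nrow(s12), 12)
  expect_true(!is.unsorted(s12$distance_from_target_mm))
  expect_true(all(s12$in_volume))
  # a trajectory leaving the volume flags samples instead of dropping them
  trx <- trajectory_spec(c(200, 0, 0), c(0, 0, 0),
                         sample_distances_mm = c(0, 60))
  sx <- simulate_biopsy_set(ph, trx)
  expect_equal(nrow(sx), 2)
  expect_false(sx$in_volume[2])
  expect_true(is.na(sx$cell_density_per_mm3[2]))
})
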