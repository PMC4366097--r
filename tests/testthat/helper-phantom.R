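# Compact phantom scaled to a small grid so unit tests stay fast; the
# geometry keeps all five tissue classes present.
test_phantom_config <- function(seed = 1L, ...) {
  phantom_config(
    dim = c(32L, 32L, 20L),
    seed = seed,
    brain_semiaxes_mm = c(26, 24, 17),
    tumor_center_mm = c(7, 4, 1),
    edema_semiaxes_mm = c(14, 12, 10),
    swi_n_blobs = 2L,
    ...
  )
}

# Single-voxel Z-spectrum volume from an analytic pool model, for spectral
# unit tests.
one_voxel_zvol <- function(pools, b0_shift = 0,
                           offsets = make_offset_grid(-4, 4, 13)) {
  z <- zspectrum_model(offsets, pools, b0_shift_ppm = b0_shift)
  zspectrum_volume(array(z, dim = c(1, 1, 1, length(offsets))), offsets)
}

default_pools <- function(noe_amp = 0.12, cfg = phantom_config()) {
  list(pool_spec(0, cfg$water_amp, cfg$water_fwhm),
       pool_spec(cfg$noe_center, noe_amp, cfg$noe_fwhm),
       pool_spec(cfg$apt_center, cfg$apt_frac * noe_amp, cfg$apt_fwhm))
}

# Location of the analytic Z-spectrum minimum for a pool set shifted by
# `b0`, by brute-force fine-grid search (the independent oracle for the
# spline-based estimator).
analytic_zmin <- function(pools, b0 = 0, halfwidth = 1.2, step = 2e-4) {
  grid <- seq(-halfwidth, halfwidth, by = step) + b0
  grid[which.min(zspectrum_model(grid, pools, b0_shift_ppm = b0))]
}
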