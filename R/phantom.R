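#' Tissue classes of the digital phantom
#'
#' Integer label codes used in the phantom's label map.
#'
#' @return Named integer vector mapping tissue names to label codes.
#' @export
tissue_labels <- function() {
  c(background = 0L, nawm = 1L, t2_edema = 2L, ce_tumor = 3L,
    necrosis = 4L, csf = 5L)
}

#' Default per-tissue contrast table
#'
#' Baseline NOE pool amplitude, mean ADC and mean cell density per tissue
#' class. The NOE amplitudes decrease from normal-appearing white matter via
#' edema to contrast-enhancing tumor and necrosis, and mean ADC increases
#' from edema towards tumor and necrosis, reproducing the region ordering of
#' both contrasts in glioblastoma. Magnitudes are free parameters of the
#' generator chosen to give plausible 7T Z-spectra and 3T ADC values.
#'
#' @return Data frame with one row per tissue class (background excluded).
#' @export
tissue_contrast_table <- function() {
  data.frame(
    tissue = c("nawm", "t2_edema", "ce_tumor", "necrosis", "csf"),
    label = c(1L, 2L, 3L, 4L, 5L),
    noe_amp = c(0.12, 0.08, 0.045, 0.02, 0.005),
    adc_mean = c(750, 1200, 1350, 1800, 3000),   # 1e-6 mm^2/s
    cell_mean = c(1000, 2000, 6000, 400, 0),     # cells/mm^3
    stringsAsFactors = FALSE
  )
}

#' Digital glioblastoma phantom configuration
#'
#' Parameters of the seeded synthetic-data generator. The geometry is a
#' brain-shaped ellipsoid of normal-appearing white matter (NAWM) with a thin
#' CSF shell, containing a concentric tumor: necrotic core inside a
#' contrast-enhancing (CE) rim inside peritumoral T2 edema. Within each
#' tissue class the NOE pool amplitude, cell density and ADC vary
#' log-normally around the class baseline, coupled through a Gaussian copula:
#'
#' * `rho_cell` is the Spearman rank correlation between cell density and the
#'   local NOE amplitude (negative by default: denser tumor, weaker NOE, so
#'   MTR_asym rises with cellularity).
#' * `rho_adc` (per class) is the Spearman rank correlation between ADC and
#'   the MTR_asym-direction latent (minus the NOE latent); it is the dial for
#'   the voxelwise MTR_asym-ADC analysis. Default: +0.25 in edema, 0
#'   elsewhere, echoing the weak positive edema correlation and the null
#'   CE-tumor result the pipeline is designed to detect.
#'
#' @param dim Grid size (3 integers, each >= 16).
#' @param voxel_size_mm Voxel edge lengths (mm); default 1.8 x 1.8 x 2.
#' @param seed Integer RNG seed; the phantom is bit-reproducible given it.
#' @param tissue_table Per-class baselines, see [tissue_contrast_table()].
#' @param water_amp,water_fwhm Central saturation dip: direct water
#'   saturation with the broad semisolid-MT background lumped in (amplitude,
#'   FWHM ppm). The default 3 ppm width reflects the broad dip of pulsed
#'   saturation at 7T and keeps the minimum resolvable on the 13-point
#'   offset grid, which a bare free-water linewidth would not be.
#' @param noe_center,noe_fwhm NOE pool center and FWHM (ppm).
#' @param apt_frac APT pool amplitude as a fraction of the local NOE
#'   amplitude.
#' @param apt_center,apt_fwhm APT pool center and FWHM (ppm).
#' @param noe_log_sd,cell_log_sd,adc_log_sd Log-normal within-class
#'   variability of the three fields.
#' @param rho_cell Rank correlation of cell density with NOE amplitude.
#' @param rho_adc Named per-class rank correlations of ADC with the
#'   MTR_asym direction (classes absent from the vector default to 0).
#' @param b0_amplitude_ppm Peak absolute value of the smooth B0 field.
#' @param brain_semiaxes_mm,csf_frac Brain ellipsoid semi-axes and the
#'   relative radius beyond which the shell is CSF.
#' @param tumor_center_mm Tumor center offset from the volume center (mm).
#' @param edema_semiaxes_mm Outer semi-axes of the edema ellipsoid (mm).
#' @param ce_frac,necrosis_frac CE rim and necrotic core outer radii as
#'   fractions of the edema semi-axes.
#' @param m0_signal Mean unsaturated signal inside the head (arbitrary
#'   units).
#' @param swi_n_blobs,swi_blob_radius_mm Number and radius of random
#'   SWI-hypointensity exclusion blobs placed inside the lesion.
#' @return An object of class `phantom_config` (a list).
#' @export
phantom_config <- function(dim = c(48L, 48L, 32L),
                           voxel_size_mm = c(1.8, 1.8, 2),
                           seed = 1L,
                           tissue_table = tissue_contrast_table(),
                           water_amp = 0.85, water_fwhm = 3.0,
                           noe_center = -3.3, noe_fwhm = 3.0,
                           apt_frac = 0.6, apt_center = 3.5, apt_fwhm = 1.5,
                           noe_log_sd = 0.15,
                           cell_log_sd = 0.35,
                           adc_log_sd = 0.10,
                           rho_cell = -0.75,
                           rho_adc = c(t2_edema = 0.25, ce_tumor = 0),
                           b0_amplitude_ppm = 0.3,
                           brain_semiaxes_mm = c(38, 36, 26),
                           csf_frac = 0.92,
                           tumor_center_mm = c(12, 6, 2),
                           edema_semiaxes_mm = c(22, 20, 16),
                           ce_frac = 0.68,
                           necrosis_frac = 0.40,
                           m0_signal = 1000,
                           swi_n_blobs = 3L,
                           swi_blob_radius_mm = 4) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 16L)) {
    stop("`dim` must be three integers, each >= 16", call. = FALSE)
  }
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (abs(rho_cell) > 0.99) stop("|rho_cell| must be <= 0.99", call. = FALSE)
  if (any(abs(rho_adc) > 0.99)) stop("|rho_adc| must be <= 0.99", call. = FALSE)
  cfg <- list(dim = dim, voxel_size_mm = voxel_size_mm, seed = as.integer(seed),
              tissue_table = tissue_table,
              water_amp = water_amp, water_fwhm = water_fwhm,
              noe_center = noe_center, noe_fwhm = noe_fwhm,
              apt_frac = apt_frac, apt_center = apt_center, apt_fwhm = apt_fwhm,
              noe_log_sd = noe_log_sd, cell_log_sd = cell_log_sd,
              adc_log_sd = adc_log_sd,
              rho_cell = rho_cell, rho_adc = rho_adc,
              b0_amplitude_ppm = b0_amplitude_ppm,
              brain_semiaxes_mm = brain_semiaxes_mm, csf_frac = csf_frac,
              tumor_center_mm = tumor_center_mm,
              edema_semiaxes_mm = edema_semiaxes_mm,
              ce_frac = ce_frac, necrosis_frac = necrosis_frac,
              m0_signal = m0_signal,
              swi_n_blobs = as.integer(swi_n_blobs),
              swi_blob_radius_mm = swi_blob_radius_mm)
  class(cfg) <- "phantom_config"
  cfg
}

# Latent Pearson correlation that yields Spearman rho_s under a Gaussian
# copula: rho_lat = 2 sin(pi rho_s / 6).
latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Seeded pairs with a prescribed rank correlation
#'
#' Draws `n` independent pairs from the generator's Gaussian copula so that
#' the population Spearman correlation of the pair equals `rho_s`. Used by
#' the phantom to couple cellularity and ADC to the NOE field, and directly
#' in calibration studies of the correlation machinery.
#'
#' @param n Number of pairs.
#' @param rho_s Target Spearman correlation in `(-1, 1)`.
#' @return A list with numeric vectors `x` and `y` (standard normal
#'   marginals; apply any monotone transform without changing ranks).
#' @export
rank_coupled_pairs <- function(n, rho_s) {
  rl <- latent_rho(rho_s)
  x <- stats::rnorm(n)
  y <- rl * x + sqrt(1 - rl^2) * stats::rnorm(n)
  list(x = x, y = y)
}

#' Build the digital glioblastoma phantom
#'
#' Deterministically (per seed) generates the aligned multi-contrast ground
#' truth the analysis pipeline consumes: tissue label map, per-voxel NOE pool
#' amplitude, cell-density and ADC fields with the configured rank
#' correlations, a smooth B0 offset field, an M0 map, and a sparse
#' SWI-hypointensity exclusion mask inside the lesion.
#'
#' @param config A [phantom_config()].
#' @return An object of class `digital_phantom`: a list with `label_map`,
#'   `noe_amp_map`, `adc_map`, `cellularity_map`, `b0_field_ppm`, `m0_map`,
#'   `swi_mask` (all arrays of shape `config$dim`), the 4x4 `affine`
#'   (voxel-center convention, 0-based indices, volume centered on the world
#'   origin), `voxel_size_mm` and the `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  tt <- config$tissue_table
  noe <- tt$noe_amp[match(c("nawm", "t2_edema", "ce_tumor", "necrosis"),
                          tt$tissue)]
  if (any(diff(noe) >= 0)) {
    stop("NOE amplitudes must decrease NAWM > edema > CE tumor > necrosis",
         call. = FALSE)
  }
  adc <- tt$adc_mean[match(c("t2_edema", "ce_tumor", "necrosis"), tt$tissue)]
  if (any(diff(adc) <= 0)) {
    stop("mean ADC must increase edema < CE tumor < necrosis", call. = FALSE)
  }
  withr::with_seed(config$seed, build_phantom_impl(config))
}

build_phantom_impl <- function(config) {
  d <- config$dim
  vs <- config$voxel_size_mm
  tt <- config$tissue_table

  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- -(d - 1) / 2 * vs

  # world coordinates of voxel centers
  xs <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * vs[1]
  ys <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * vs[2]
  zs <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) * vs[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  a <- config$brain_semiaxes_mm
  r_brain <- sqrt((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2)
  label <- array(0L, dim = d)
  label[r_brain <= 1] <- 5L                       # CSF shell
  label[r_brain <= config$csf_frac] <- 1L         # NAWM

  tc <- config$tumor_center_mm
  e <- config$edema_semiaxes_mm
  r_tum <- sqrt(((X - tc[1]) / e[1])^2 + ((Y - tc[2]) / e[2])^2 +
                  ((Z - tc[3]) / e[3])^2)
  inside_wm <- label == 1L
  label[inside_wm & r_tum <= 1] <- 2L             # T2 edema
  label[inside_wm & r_tum <= config$ce_frac] <- 3L
  label[inside_wm & r_tum <= config$necrosis_frac] <- 4L

  n <- prod(d)
  lab <- as.vector(label)

  # Gaussian-copula latents: z1 drives NOE amplitude; cellularity couples to
  # z1 at rho_cell; ADC couples to the MTR_asym direction (-z1) at the
  # class-specific rho_adc.
  z1 <- stats::rnorm(n)
  rc <- latent_rho(config$rho_cell)
  z2 <- rc * z1 + sqrt(1 - rc^2) * stats::rnorm(n)
  rho_adc_class <- rep(0, 6)
  names(rho_adc_class) <- names(tissue_labels())
  ra_cfg <- config$rho_adc
  rho_adc_class[names(ra_cfg)] <- ra_cfg
  ra <- latent_rho(rho_adc_class[lab + 1L])
  z3 <- ra * (-z1) + sqrt(1 - ra^2) * stats::rnorm(n)

  base_noe <- base_cell <- base_adc <- rep(0, n)
  for (k in seq_len(nrow(tt))) {
    sel <- lab == tt$label[k]
    base_noe[sel] <- tt$noe_amp[k]
    base_cell[sel] <- tt$cell_mean[k]
    base_adc[sel] <- tt$adc_mean[k]
  }
  lnorm <- function(zz, s) exp(s * zz - s^2 / 2)
  noe_amp <- base_noe * lnorm(z1, config$noe_log_sd)
  cellularity <- base_cell * lnorm(z2, config$cell_log_sd)
  adc_map <- base_adc * lnorm(z3, config$adc_log_sd)
  cellularity[lab %in% c(0L, 5L)] <- 0   # background and CSF are acellular

  # Smooth B0 field: random low-order polynomial plus one Gaussian bump,
  # rescaled so the peak deviation equals b0_amplitude_ppm.
  Xn <- X / max(abs(xs)); Yn <- Y / max(abs(ys)); Zn <- Z / max(abs(zs))
  g <- stats::rnorm(3)
  q <- stats::rnorm(2, sd = 0.5)
  bump_c <- stats::runif(3, -0.4, 0.4) * c(max(xs), max(ys), max(zs))
  bump_w <- 0.25 * c(max(xs), max(ys), max(zs)) * 2
  bump <- 1.5 * exp(-(((X - bump_c[1]) / bump_w[1])^2 +
                        ((Y - bump_c[2]) / bump_w[2])^2 +
                        ((Z - bump_c[3]) / bump_w[3])^2) / 2)
  raw <- g[1] * Xn + g[2] * Yn + g[3] * Zn + q[1] * (Xn^2 - Yn^2) +
    q[2] * Xn * Yn + bump
  b0 <- config$b0_amplitude_ppm * raw / max(abs(raw))

  m0 <- rep(0, n)
  m0[lab != 0L] <- config$m0_signal * lnorm(stats::rnorm(sum(lab != 0L)), 0.03)

  # SWI-hypointensity stand-in: a few random spherical blobs in the lesion
  # (edema or CE rim), as micro-bleed exclusion zones.
  swi <- array(FALSE, dim = d)
  lesion_idx <- which(lab %in% c(2L, 3L))
  if (config$swi_n_blobs > 0 && length(lesion_idx) > 0) {
    centers <- sample(lesion_idx, config$swi_n_blobs)
    for (ci in centers) {
      dist2 <- (X - X[ci])^2 + (Y - Y[ci])^2 + (Z - Z[ci])^2
      swi[dist2 <= config$swi_blob_radius_mm^2] <- TRUE
    }
  }

  structure(
    list(label_map = label,
         noe_amp_map = array(noe_amp, dim = d),
         adc_map = array(adc_map, dim = d),
         cellularity_map = array(cellularity, dim = d),
         b0_field_ppm = b0,
         m0_map = array(m0, dim = d),
         swi_mask = swi,
         affine = affine,
         voxel_size_mm = vs,
         config = config),
    class = "digital_phantom"
  )
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$label_map)
  cat(sprintf("Digital glioblastoma phantom %dx%dx%d (%.1fx%.1fx%.1f mm)\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3]))
  tl <- tissue_labels()
  cnt <- vapply(tl, function(v) sum(x$label_map == v), integer(1))
  cat("  voxels per class: ",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  cat(sprintf("  B0 field within +/- %.3g ppm, seed %d\n",
              max(abs(x$b0_field_ppm)), x$config$seed))
  invisible(x)
}

#' Noise-free Z-spectrum ground truth of a phantom
#'
#' Evaluates the multi-pool Lorentzian model at each voxel: direct water
#' saturation plus the voxel's NOE pool and its proportional APT pool,
#' optionally shifted by the phantom's B0 field. This is the analytic oracle
#' that acquisition simulation and processing are checked against.
#'
#' @param phantom A [build_phantom()] result.
#' @param offsets_ppm Offsets at which to evaluate.
#' @param apply_b0 Shift each voxel's spectrum by its B0 deviation
#'   (default TRUE). Use FALSE for the unshifted truth.
#' @return 4D array (x, y, z, offset) of noise-free Z values; background
#'   voxels (no water pool) are 1.
#' @export
zspectrum_truth <- function(phantom, offsets_ppm, apply_b0 = TRUE) {
  stopifnot(inherits(phantom, "digital_phantom"))
  cfg <- phantom$config
  d <- dim(phantom$label_map)
  noe <- as.vector(phantom$noe_amp_map)
  b0 <- if (apply_b0) as.vector(phantom$b0_field_ppm) else rep(0, prod(d))
  head_voxel <- as.vector(phantom$label_map) != 0L
  out <- array(1, dim = c(d, length(offsets_ppm)))
  for (k in seq_along(offsets_ppm)) {
    x <- offsets_ppm[k] - b0
    zk <- rep(1, prod(d))
    zk[head_voxel] <- 1 -
      cfg$water_amp * lorentzian(x[head_voxel], 0, cfg$water_fwhm) -
      noe[head_voxel] * lorentzian(x[head_voxel], cfg$noe_center,
                                   cfg$noe_fwhm) -
      cfg$apt_frac * noe[head_voxel] *
        lorentzian(x[head_voxel], cfg$apt_center, cfg$apt_fwhm)
    out[, , , k] <- zk
  }
  out
}

#' Analytic MTR asymmetry ground truth of a phantom
#'
#' Closed-form `100 * (Z(-readout) - Z(+readout))` from the phantom's pools
#' with no B0 shift (i.e. the value a perfect B0 correction should recover).
#' The water pool is symmetric about 0 and cancels exactly, so the truth is
#' proportional to the per-voxel NOE amplitude.
#'
#' @param phantom A [build_phantom()] result.
#' @param readout_ppm Readout offset magnitude (ppm), default `10/3`.
#' @return 3D array of MTR_asym in percent (0 in background).
#' @export
mtr_asym_truth <- function(phantom, readout_ppm = 10 / 3) {
  stopifnot(inherits(phantom, "digital_phantom"))
  cfg <- phantom$config
  noe <- phantom$noe_amp_map
  # Z(-r) - Z(+r); water cancels by symmetry.
  per_unit <-
    (lorentzian(readout_ppm, cfg$noe_center, cfg$noe_fwhm) -
       lorentzian(-readout_ppm, cfg$noe_center, cfg$noe_fwhm)) +
    cfg$apt_frac * (lorentzian(readout_ppm, cfg$apt_center, cfg$apt_fwhm) -
                      lorentzian(-readout_ppm, cfg$apt_center, cfg$apt_fwhm))
  out <- 100 * noe * per_unit
  out[phantom$label_map == 0L] <- 0
  out
}
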