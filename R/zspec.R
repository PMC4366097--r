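#' Z-spectrum volume
#'
#' Container for a normalized 4D Z-spectrum stack: `Z = M/M0` per voxel and
#' saturation offset, with its offset axis, affine and analyzable-voxel
#' mask.
#'
#' @param data 4D array (x, y, z, offset) of Z values.
#' @param offsets_ppm Strictly increasing offset axis matching the 4th
#'   dimension.
#' @param affine 4x4 voxel-to-world transform (voxel-center convention,
#'   0-based indices).
#' @param mask 3D logical array of analyzable voxels (default: all finite
#'   spectra).
#' @return An object of class `zspectrum_volume`.
#' @export
zspectrum_volume <- function(data, offsets_ppm, affine = diag(4),
                             mask = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be 4D", call. = FALSE)
  if (length(offsets_ppm) != dim(data)[4]) {
    stop("offset axis length must match the 4th dimension", call. = FALSE)
  }
  if (is.unsorted(offsets_ppm, strictly = TRUE)) {
    stop("`offsets_ppm` must be strictly increasing", call. = FALSE)
  }
  if (!is.matrix(affine) || any(dim(affine) != 4) ||
      abs(det(affine)) < 1e-12) {
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  }
  d <- dim(data)[1:3]
  if (is.null(mask)) {
    mask <- array(apply(is.finite(data), c(1, 2, 3), all), dim = d)
  }
  stopifnot(all(dim(mask) == d))
  structure(list(data = data, offsets_ppm = as.numeric(offsets_ppm),
                 affine = affine, mask = mask),
            class = "zspectrum_volume")
}

#' @export
print.zspectrum_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Z-spectrum volume %dx%dx%d, %d offsets (%.3g .. %.3g ppm)\n",
              d[1], d[2], d[3], d[4], min(x$offsets_ppm), max(x$offsets_ppm)))
  cat(sprintf("  %d / %d voxels in mask\n", sum(x$mask), prod(d[1:3])))
  invisible(x)
}

#' Normalize a saturated stack by the unsaturated M0 image
#'
#' Computes `Z = M/M0` voxelwise. Voxels whose M0 falls below a relative
#' floor (default 5% of the robust M0 maximum, the 99th percentile) are
#' excluded from the mask rather than zeroed: background noise voxels would
#' otherwise produce unbounded Z values.
#'
#' @param sat 4D saturated stack, or a [simulate_acquisition()] result (in
#'   which case `m0`, `offsets_ppm` and `affine` are taken from it).
#' @param m0 3D unsaturated volume.
#' @param offsets_ppm Offset axis of the stack.
#' @param affine 4x4 voxel-to-world transform.
#' @param m0_floor Relative M0 floor for masking.
#' @return A [zspectrum_volume()].
#' @export
normalize_zspectrum <- function(sat, m0 = NULL, offsets_ppm = NULL,
                                affine = diag(4), m0_floor = 0.05) {
  if (inherits(sat, "cest_acquisition")) {
    acqn <- sat
    sat <- acqn$sat; m0 <- acqn$m0
    offsets_ppm <- acqn$offsets_ppm; affine <- acqn$affine
  }
  if (length(dim(sat)) != 4L) stop("`sat` must be 4D", call. = FALSE)
  if (!all(dim(sat)[1:3] == dim(m0))) {
    stop("`sat` and `m0` must share their spatial shape", call. = FALSE)
  }
  floor_abs <- m0_floor * stats::quantile(m0, 0.99, names = FALSE)
  mask <- is.finite(m0) & m0 > floor_abs
  z <- sat / as.vector(m0)   # recycles m0 across the offset dimension
  z[!is.finite(z)] <- NA_real_
  mask <- mask & array(apply(is.finite(z), c(1, 2, 3), all), dim = dim(m0))
  zspectrum_volume(z, offsets_ppm, affine, mask)
}

# Weight matrix of natural cubic spline interpolation from `offsets` onto
# `grid`: interpolation is linear in the ordinates, so row i holds the
# weights giving the spline value at grid[i] from the 13 (or so) samples.
spline_weights <- function(offsets, grid) {
  n <- length(offsets)
  W <- matrix(0, nrow = length(grid), ncol = n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    W[, j] <- stats::splinefun(offsets, e, method = "natural")(grid)
  }
  W
}

# Masked voxel spectra as an n_voxel x n_offset matrix.
masked_matrix <- function(z) {
  idx <- which(z$mask)
  nvox <- prod(dim(z$data)[1:3])
  mat <- matrix(z$data, nrow = nvox)[idx, , drop = FALSE]
  list(idx = idx, mat = mat)
}

#' Map B0 deviations by spline-minimum search
#'
#' Per masked voxel, interpolates the Z-spectrum with a natural cubic spline
#' and takes the argmin on a dense grid within a symmetric search window
#' around 0 ppm as the water-center deviation. A voxel is flagged invalid
#' when its minimum lands on the search-window boundary (the true minimum
#' then lies outside the window and the estimate would be censored).
#'
#' @param z A [zspectrum_volume()].
#' @param search_halfwidth_ppm Half-width of the minimum search window
#'   (default 1 ppm, comfortably covering 7T inhomogeneity while keeping the
#'   minimum away from the sampled range boundary).
#' @param grid_step_ppm Dense evaluation step (default 0.001 ppm, well below
#'   all tolerances used downstream).
#' @return An object of class `b0_map`: list with `delta_ppm` (3D, NA
#'   outside mask), `valid` (3D logical) and `search_halfwidth_ppm`.
#' @export
estimate_b0 <- function(z, search_halfwidth_ppm = 1, grid_step_ppm = 0.001) {
  stopifnot(inherits(z, "zspectrum_volume"))
  off <- z$offsets_ppm
  if (length(off) < 4L) {
    stop("at least 4 offsets are required for cubic-spline interpolation",
         call. = FALSE)
  }
  if (min(off) > -search_halfwidth_ppm || max(off) < search_halfwidth_ppm) {
    stop("offsets must span the search window around 0 ppm", call. = FALSE)
  }
  grid <- seq(-search_halfwidth_ppm, search_halfwidth_ppm,
              by = grid_step_ppm)
  W <- t(spline_weights(off, grid))      # n_offset x n_grid
  mm <- masked_matrix(z)
  d <- dim(z$data)[1:3]
  delta <- array(NA_real_, dim = d)
  valid <- array(FALSE, dim = d)
  ng <- length(grid)
  chunk <- 4000L
  for (start in seq(1L, length(mm$idx), by = chunk)) {
    rows <- start:min(start + chunk - 1L, length(mm$idx))
    dense <- mm$mat[rows, , drop = FALSE] %*% W
    amin <- max.col(-dense, ties.method = "first")
    delta[mm$idx[rows]] <- grid[amin]
    valid[mm$idx[rows]] <- amin > 1L & amin < ng
  }
  structure(list(delta_ppm = delta, valid = valid,
                 search_halfwidth_ppm = search_halfwidth_ppm),
            class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  ok <- x$valid & is.finite(x$delta_ppm)
  cat(sprintf("B0 deviation map: %d valid voxels, range %.3g .. %.3g ppm\n",
              sum(ok), min(x$delta_ppm[ok]), max(x$delta_ppm[ok])))
  invisible(x)
}

#' Re-center Z-spectra using a B0 deviation map
#'
#' Per voxel, re-interpolates the natural cubic spline of the spectrum at
#' `offsets + delta` so the corrected spectrum's minimum sits at 0 ppm.
#' Requested points falling outside the acquired offset range are set
#' non-finite (the spline is never extrapolated: extrapolation would
#' fabricate asymmetry). Voxels with an invalid B0 estimate pass through
#' unshifted but are dropped from the mask.
#'
#' @param z A [zspectrum_volume()].
#' @param b0 A [estimate_b0()] result on the same grid.
#' @return A corrected [zspectrum_volume()] whose mask excludes invalid-B0
#'   voxels.
#' @export
correct_b0 <- function(z, b0) {
  stopifnot(inherits(z, "zspectrum_volume"), inherits(b0, "b0_map"))
  d <- dim(z$data)[1:3]
  if (!all(dim(b0$delta_ppm) == d)) {
    stop("B0 map shape does not match the Z-spectrum volume", call. = FALSE)
  }
  off <- z$offsets_ppm
  lo <- min(off); hi <- max(off)
  out <- z$data
  nvox <- prod(d)
  mat <- matrix(z$data, nrow = nvox)
  idx <- which(z$mask & b0$valid)
  for (i in idx) {
    delta <- b0$delta_ppm[i]
    if (!is.finite(delta) || delta == 0) next
    target <- off + delta
    sf <- stats::splinefun(off, mat[i, ], method = "natural")
    vals <- sf(target)
    vals[target < lo | target > hi] <- NA_real_
    out[((seq_along(off) - 1L) * nvox) + i] <- vals
  }
  zspectrum_volume(out, off, z$affine, mask = z$mask & b0$valid)
}

#' MTR asymmetry map at a readout offset
#'
#' Computes `100 * (Z(-readout) - Z(+readout))` per masked voxel by natural
#' cubic-spline interpolation of the (corrected) spectrum. On the 13-point
#' grid between -4 and +4 ppm the readout `10/3 ~ 3.33 ppm` falls exactly on
#' grid nodes, reconciling the equidistant grid with the nominal 3.3 ppm
#' readout. Upfield NOE dips exceeding the downfield dips make the value
#' negative; weak NOE appears as high (less negative) MTR_asym.
#'
#' Voxels whose corrected spectrum is non-finite at offsets needed to
#' bracket the readout (after a large B0 shift pushed them off the acquired
#' range) come out NA and are excluded downstream.
#'
#' @param z A (B0-corrected) [zspectrum_volume()].
#' @param readout_ppm Readout offset magnitude (ppm), default `10/3`.
#' @param window Display clip range in percent, stored for rendering only.
#' @return An object of class `mtr_asym_map`: list with `values_percent`
#'   (3D, NA where unavailable), `readout_ppm`, `window`.
#' @export
compute_mtr_asym <- function(z, readout_ppm = 10 / 3, window = c(-10, 5)) {
  stopifnot(inherits(z, "zspectrum_volume"))
  off <- z$offsets_ppm
  if (readout_ppm <= 0) stop("`readout_ppm` must be > 0", call. = FALSE)
  tol <- 1e-9  # absorb one-ULP differences between grid nodes and readout
  if (-readout_ppm < min(off) - tol || readout_ppm > max(off) + tol) {
    stop("readout offset outside the acquired range", call. = FALSE)
  }
  mm <- masked_matrix(z)
  d <- dim(z$data)[1:3]
  values <- array(NA_real_, dim = d)
  if (length(mm$idx) > 0) {
    fin <- is.finite(mm$mat)
    pattern <- apply(fin, 1L, function(r) paste(as.integer(r), collapse = ""))
    for (pat in unique(pattern)) {
      rows <- which(pattern == pat)
      cols <- which(fin[rows[1], ])
      if (length(cols) < 4L) next
      sub_off <- off[cols]
      if (min(sub_off) - tol > -readout_ppm ||
          max(sub_off) + tol < readout_ppm) next
      W <- spline_weights(sub_off, c(-readout_ppm, readout_ppm))
      vals <- mm$mat[rows, cols, drop = FALSE] %*% t(W)
      values[mm$idx[rows]] <- 100 * (vals[, 1] - vals[, 2])
    }
  }
  structure(list(values_percent = values, readout_ppm = readout_ppm,
                 window = window),
            class = "mtr_asym_map")
}

#' @export
print.mtr_asym_map <- function(x, ...) {
  ok <- is.finite(x$values_percent)
  cat(sprintf(
    "MTR_asym map at %.3g ppm: %d voxels, %.2f%% .. %.2f%% (window %g..%g)\n",
    x$readout_ppm, sum(ok), min(x$values_percent[ok]),
    max(x$values_percent[ok]), x$window[1], x$window[2]))
  invisible(x)
}

#' Clip an MTR asymmetry map to its display window
#'
#' Clips values to `[lo, hi]` percent for rendering. Statistics elsewhere in
#' the package always use the unclipped values: clipping destroys ranks in
#' the tails.
#'
#' @param m An [compute_mtr_asym()] result or a numeric array of percent
#'   values.
#' @param lo,hi Window bounds in percent (default -10 and 5).
#' @return Clipped numeric array of the same shape.
#' @export
window_display <- function(m, lo = -10, hi = 5) {
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  v <- if (inherits(m, "mtr_asym_map")) m$values_percent else m
  pmin(pmax(v, lo), hi)
}
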