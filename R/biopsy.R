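#' Convert world coordinates to a voxel index
#'
#' Nearest-voxel index under the inverse affine, voxel-center convention,
#' 0-based (the NIfTI voxel convention; add 1 before indexing R arrays).
#'
#' @param world_mm Numeric 3-vector of world coordinates (mm).
#' @param affine 4x4 voxel-to-world transform.
#' @param dim Optional volume dimensions; when given, an index outside the
#'   volume is an error.
#' @return Integer 3-vector of 0-based voxel indices.
#' @examples
#' world_to_voxel(c(4, 4, 4), diag(c(2, 2, 2, 1))) # (2, 2, 2)
#' @export
world_to_voxel <- function(world_mm, affine, dim = NULL) {
  stopifnot(length(world_mm) == 3L, all(dim(affine) == 4))
  if (abs(det(affine)) < 1e-12) stop("`affine` must be invertible",
                                     call. = FALSE)
  v <- solve(affine, c(world_mm, 1))[1:3]
  idx <- as.integer(round(v))
  if (!is.null(dim) && (any(idx < 0L) || any(idx > dim - 1L))) {
    stop(sprintf("voxel index (%s) outside the volume",
                 paste(idx, collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Convert a voxel index to world coordinates
#'
#' @param voxel 0-based integer 3-vector.
#' @param affine 4x4 voxel-to-world transform.
#' @return Numeric 3-vector of world coordinates (mm).
#' @export
voxel_to_world <- function(voxel, affine) {
  stopifnot(length(voxel) == 3L, all(dim(affine) == 4))
  (affine %*% c(voxel, 1))[1:3]
}

#' Neighborhood mean around a voxel
#'
#' Mean over the `(2r+1)^3` cube centered on a voxel (27 voxels at the
#' default radius 1, matching the biopsy-site readout that averages the
#' surrounding 3x3x3 voxels to absorb spatial inaccuracy). The cube is
#' clipped at the volume boundary and non-finite voxels are excluded; the
#' number of voxels actually used is reported.
#'
#' @param map 3D numeric array.
#' @param center 0-based integer 3-vector inside the volume.
#' @param radius Cube half-width in voxels (default 1).
#' @return List with `mean` (NA if every cube voxel is non-finite) and
#'   `n_used`.
#' @export
neighborhood_mean <- function(map, center, radius = 1L) {
  d <- dim(map)
  stopifnot(length(d) == 3L, length(center) == 3L)
  if (any(center < 0L) || any(center > d - 1L)) {
    stop("`center` must lie inside the volume", call. = FALSE)
  }
  c1 <- center + 1L  # to 1-based
  rng <- lapply(1:3, function(ax) {
    max(1L, c1[ax] - radius):min(d[ax], c1[ax] + radius)
  })
  cube <- map[rng[[1]], rng[[2]], rng[[3]]]
  ok <- is.finite(cube)
  if (!any(ok)) {
    warning("all neighborhood voxels are non-finite")
    return(list(mean = NA_real_, n_used = 0L))
  }
  list(mean = mean(cube[ok]), n_used = sum(ok))
}

#' Stereotactic biopsy trajectory
#'
#' A straight path from a skull entry point to an image-defined target,
#' with specimens taken at recorded distances from the target (measured
#' back along the trajectory towards the entry; negative distances overshoot
#' the target).
#'
#' @param entry_world_mm,target_world_mm World coordinates (mm) of the entry
#'   and target points; must differ.
#' @param sample_distances_mm Sorted signed distances from the target (mm)
#'   at which specimens are taken; default 12 samples every 2 mm from the
#'   target.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(entry_world_mm, target_world_mm,
                            sample_distances_mm = seq(0, 22, by = 2)) {
  stopifnot(length(entry_world_mm) == 3L, length(target_world_mm) == 3L)
  if (all(entry_world_mm == target_world_mm)) {
    stop("entry and target points must differ", call. = FALSE)
  }
  if (length(sample_distances_mm) < 1L ||
      is.unsorted(sample_distances_mm)) {
    stop("`sample_distances_mm` must be a sorted non-empty vector",
         call. = FALSE)
  }
  structure(list(entry_world_mm = as.numeric(entry_world_mm),
                 target_world_mm = as.numeric(target_world_mm),
                 n_samples = length(sample_distances_mm),
                 sample_distances_mm = as.numeric(sample_distances_mm)),
            class = "trajectory_spec")
}

#' Default biopsy trajectory for a phantom
#'
#' Targets the middle of the contrast-enhancing rim along the +y axis, with
#' the specimen series straddling the target (negative distances overshoot
#' towards the necrotic core, positive distances run back towards the
#' entry), so a 12-specimen series crosses necrotic, contrast-enhancing and
#' non-enhancing tissue like a clinical series while staying inside the
#' brain.
#'
#' @param phantom A [build_phantom()] result.
#' @param n_samples Number of specimens (default 12).
#' @param spacing_mm Distance between consecutive specimens (default 2 mm).
#' @return A [trajectory_spec()].
#' @export
default_trajectory <- function(phantom, n_samples = 12L, spacing_mm = 2) {
  cfg <- phantom$config
  tc <- cfg$tumor_center_mm
  # target mid-way through the CE shell along +y
  r_mid <- cfg$edema_semiaxes_mm[2] *
    (cfg$necrosis_frac + cfg$ce_frac) / 2
  target <- tc + c(0, r_mid, 0)
  entry <- c(tc[1], cfg$brain_semiaxes_mm[2] * 0.98, tc[3])
  start <- -floor(n_samples / 3) * spacing_mm
  trajectory_spec(entry, target,
                  sample_distances_mm = seq(start, by = spacing_mm,
                                            length.out = n_samples))
}

#' Simulate a biopsy series along a trajectory
#'
#' Places specimens on the entry-target line at the trajectory's recorded
#' distances and reads the phantom's cell density there (nearest voxel),
#' optionally perturbed by multiplicative log-normal sampling noise.
#' Positions falling outside the volume are flagged (`in_volume = FALSE`,
#' density NA), never silently dropped.
#'
#' @param phantom A [build_phantom()] result.
#' @param traj A [trajectory_spec()]; default [default_trajectory()].
#' @param seed RNG seed for the sampling noise.
#' @param cell_noise_cv Coefficient of variation of the multiplicative
#'   sampling noise (0 = exact map lookup).
#' @return Data frame with columns `sample_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `distance_from_target_mm`, `cell_density_per_mm3`, `region_tag`,
#'   `in_volume`.
#' @export
simulate_biopsy_set <- function(phantom, traj = default_trajectory(phantom),
                                seed = 1L, cell_noise_cv = 0.05) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(traj, "trajectory_spec"))
  d <- dim(phantom$label_map)
  u <- traj$entry_world_mm - traj$target_world_mm
  u <- u / sqrt(sum(u^2))
  tags <- c("contrast-enhancing" = 3L, "necrotic" = 4L)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(traj$n_samples), function(i) {
      pos <- traj$target_world_mm + traj$sample_distances_mm[i] * u
      idx <- try(world_to_voxel(pos, phantom$affine, dim = d), silent = TRUE)
      if (inherits(idx, "try-error")) {
        return(data.frame(sample_id = i, x_mm = pos[1], y_mm = pos[2],
                          z_mm = pos[3],
                          distance_from_target_mm = traj$sample_distances_mm[i],
                          cell_density_per_mm3 = NA_real_,
                          region_tag = NA_character_, in_volume = FALSE,
                          stringsAsFactors = FALSE))
      }
      i1 <- idx + 1L
      dens <- phantom$cellularity_map[i1[1], i1[2], i1[3]]
      if (cell_noise_cv > 0) {
        dens <- dens * exp(cell_noise_cv * stats::rnorm(1) -
                             cell_noise_cv^2 / 2)
      }
      lab <- phantom$label_map[i1[1], i1[2], i1[3]]
      tag <- names(tags)[match(lab, tags)]
      if (is.na(tag)) tag <- "non-enhancing"
      data.frame(sample_id = i, x_mm = pos[1], y_mm = pos[2], z_mm = pos[3],
                 distance_from_target_mm = traj$sample_distances_mm[i],
                 cell_density_per_mm3 = dens, region_tag = tag,
                 in_volume = TRUE, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Attach neighborhood MRI readouts to biopsy samples
#'
#' For each in-volume sample, averages the MTR_asym and ADC maps over the
#' surrounding 3x3x3 voxel cube at the biopsy position.
#'
#' @param samples A [simulate_biopsy_set()] table (or any table with
#'   `x_mm`, `y_mm`, `z_mm`, `in_volume`).
#' @param mtr An [compute_mtr_asym()] result or 3D percent array.
#' @param adc 3D ADC map.
#' @param affine 4x4 voxel-to-world transform of the maps.
#' @param radius Neighborhood radius in voxels (default 1 = 3x3x3).
#' @return `samples` with added columns `mtr_asym_mean_percent`, `adc_mean`,
#'   `n_voxels_used`.
#' @export
add_biopsy_readouts <- function(samples, mtr, adc, affine, radius = 1L) {
  v <- if (inherits(mtr, "mtr_asym_map")) mtr$values_percent else mtr
  d <- dim(v)
  samples$mtr_asym_mean_percent <- NA_real_
  samples$adc_mean <- NA_real_
  samples$n_voxels_used <- 0L
  for (i in seq_len(nrow(samples))) {
    if (!isTRUE(samples$in_volume[i])) next
    pos <- c(samples$x_mm[i], samples$y_mm[i], samples$z_mm[i])
    idx <- world_to_voxel(pos, affine, dim = d)
    nm <- neighborhood_mean(v, idx, radius)
    na <- neighborhood_mean(adc, idx, radius)
    samples$mtr_asym_mean_percent[i] <- nm$mean
    samples$adc_mean[i] <- na$mean
    samples$n_voxels_used[i] <- nm$n_used
  }
  samples
}

#' Correlate biopsy cell density with the co-located MRI readouts
#'
#' Spearman correlation of cell density against the neighborhood-averaged
#' MTR_asym and ADC, plus an ordinary least-squares fit of density on each
#' contrast (slope, intercept, R-squared, regression p from the F test).
#'
#' @param samples A biopsy table with `cell_density_per_mm3`,
#'   `mtr_asym_mean_percent` and `adc_mean` columns.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame with one row per contrast (`mtr_asym`, `adc`):
#'   `r_sp`, `p`, `n`, `significant`, `slope`, `intercept`, `r_squared`,
#'   `p_regression`.
#' @export
correlate_biopsies <- function(samples, alpha = 0.05) {
  need <- c("cell_density_per_mm3", "mtr_asym_mean_percent", "adc_mean")
  stopifnot(all(need %in% names(samples)))
  rows <- lapply(c(mtr_asym = "mtr_asym_mean_percent", adc = "adc_mean"),
                 function(col) {
    ok <- is.finite(samples$cell_density_per_mm3) &
      is.finite(samples[[col]])
    if (sum(ok) < 5L) {
      stop("fewer than 5 biopsy samples with complete values", call. = FALSE)
    }
    dens <- samples$cell_density_per_mm3[ok]
    x <- samples[[col]][ok]
    sp <- spearman_rs(x, dens)
    fit <- stats::lm(dens ~ x)
    sm <- summary(fit)
    preg <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    data.frame(r_sp = sp$r, p = sp$p, n = sp$n,
               significant = sp$p < alpha,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared, p_regression = unname(preg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(contrast = names(rows), out)
  rownames(out) <- NULL
  out
}
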