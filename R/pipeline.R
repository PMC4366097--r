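#' Full-run configuration
#'
#' Bundles the seed, phantom and acquisition settings and the analysis
#' options for one reproducible end-to-end run. Values can also be loaded
#' from a YAML file via [load_run_config()]; unspecified fields keep their
#' defaults.
#'
#' @param seed Master seed; the phantom, acquisition noise and biopsy
#'   sampling derive their seeds from it.
#' @param phantom A [phantom_config()] (its own seed is overridden by
#'   `seed`).
#' @param acq An [acquisition_params()].
#' @param alpha Significance level for all tests.
#' @param readout_ppm MTR_asym readout offset magnitude (ppm).
#' @param b0_search_halfwidth_ppm B0 minimum-search half-width (ppm).
#' @param bands Association-class magnitude band edges, see
#'   [classify_association()].
#' @param n_biopsies,biopsy_spacing_mm Biopsy series geometry.
#' @param patient_id Identifier written into the result tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       phantom = phantom_config(),
                       acq = acquisition_params(),
                       alpha = 0.05,
                       readout_ppm = 10 / 3,
                       b0_search_halfwidth_ppm = 1,
                       bands = c(negligible = 0.15, weak = 0.40,
                                 moderate = 0.65),
                       n_biopsies = 12L,
                       biopsy_spacing_mm = 2,
                       patient_id = "sim01") {
  if (is.unsorted(bands, strictly = TRUE)) {
    stop("`bands` must be strictly increasing", call. = FALSE)
  }
  phantom$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), phantom = phantom, acq = acq,
                 alpha = alpha, readout_ppm = readout_ppm,
                 b0_search_halfwidth_ppm = b0_search_halfwidth_ppm,
                 bands = bands, n_biopsies = as.integer(n_biopsies),
                 biopsy_spacing_mm = biopsy_spacing_mm,
                 patient_id = patient_id),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys override [run_config()] defaults;
#' `phantom:` and `acquisition:` sub-maps override the respective component
#' defaults field by field.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  ph_args <- y$phantom %||% list()
  if (!is.null(ph_args$rho_adc)) ph_args$rho_adc <- unlist(ph_args$rho_adc)
  phantom <- do.call(phantom_config, ph_args)
  acq_args <- y$acquisition %||% list()
  if (!is.null(acq_args$offsets_ppm)) {
    acq_args$offsets_ppm <- as.numeric(unlist(acq_args$offsets_ppm))
  }
  acq <- do.call(acquisition_params, acq_args)
  top <- y[setdiff(names(y), c("phantom", "acquisition"))]
  if (!is.null(top$bands)) top$bands <- unlist(top$bands)
  do.call(run_config, c(list(phantom = phantom, acq = acq), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-process-correlate-biopsy pipeline
#'
#' Executes every stage in order on one synthetic subject: phantom
#' generation, CEST acquisition, normalization, B0 mapping and correction,
#' MTR_asym computation, ROI exclusion handling, the voxelwise
#' MTR_asym-ADC correlation per ROI, and the biopsy-series analysis. Writes
#' `table1.csv` (per-ROI correlation rows), `table2.csv` (biopsy
#' correlations), `fig5_points.csv` (per-specimen readouts), the MTR_asym
#' and B0 maps as NIfTI, and a JSON manifest with the seed, package version,
#' per-stage voxel accounting and output list. Re-running with the same
#' configuration reproduces every output except the manifest timestamp. On
#' any stage failure the partial outputs of this run are removed and the
#' error names the stage.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [load_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param write_dataset Also write the simulated input dataset under
#'   `<out_dir>/dataset` (default FALSE).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         write_dataset = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  stage <- "setup"
  result <- tryCatch({
    stage <- "phantom"
    phantom <- build_phantom(config$phantom)

    stage <- "acquisition"
    acq <- simulate_acquisition(phantom, config$acq, seed = config$seed + 1L)

    stage <- "normalization"
    z <- normalize_zspectrum(acq)
    n_head <- sum(phantom$label_map != 0L)
    n_masked <- sum(z$mask)

    stage <- "b0_estimation"
    b0 <- estimate_b0(z, config$b0_search_halfwidth_ppm)

    stage <- "b0_correction"
    zc <- correct_b0(z, b0)

    stage <- "mtr_asym"
    mtr <- compute_mtr_asym(zc, config$readout_ppm)

    stage <- "rois"
    lab <- phantom$label_map
    rois <- roi_mask_set(ce_t1_tumor = lab == 3L, t2_edema = lab == 2L,
                         swi_exclusion = phantom$swi_mask,
                         necrosis = lab == 4L)
    roi_before <- c(ce_t1_tumor = sum(rois$ce_t1_tumor),
                    t2_edema = sum(rois$t2_edema))
    clean <- apply_exclusions(rois)
    roi_after <- c(ce_t1_tumor = sum(clean$ce_t1_tumor),
                   t2_edema = sum(clean$t2_edema))

    stage <- "voxelwise_correlation"
    pairs <- extract_pairs(mtr, phantom$adc_map, clean)
    table1 <- correlate_rois(pairs, config$alpha)
    table1 <- cbind(patient = config$patient_id, table1)

    stage <- "biopsy"
    traj <- default_trajectory(phantom, config$n_biopsies,
                               config$biopsy_spacing_mm)
    samples <- simulate_biopsy_set(phantom, traj, seed = config$seed + 2L)
    samples <- add_biopsy_readouts(samples, mtr, phantom$adc_map,
                                   phantom$affine)
    table2 <- correlate_biopsies(samples, config$alpha)
    table2 <- cbind(patient = config$patient_id, table2)

    stage <- "outputs"
    utils::write.csv(table1, note(file.path(out_dir, "table1.csv")),
                     row.names = FALSE)
    utils::write.csv(table2, note(file.path(out_dir, "table2.csv")),
                     row.names = FALSE)
    utils::write.csv(samples, note(file.path(out_dir, "fig5_points.csv")),
                     row.names = FALSE)
    write_nifti_map(mtr$values_percent, phantom$affine,
                    note(file.path(out_dir, "mtr_asym.nii.gz")))
    write_nifti_map(b0$delta_ppm, phantom$affine,
                    note(file.path(out_dir, "b0_deviation.nii.gz")))
    if (write_dataset) {
      ds <- write_cest_dataset(acq, phantom, file.path(out_dir, "dataset"),
                               biopsies = samples)
      written <- c(written, unname(ds))
    }

    dropped <- attr(pairs, "n_dropped")
    manifest <- list(
      package = "noecest",
      version = as.character(utils::packageVersion("noecest")),
      seed = config$seed,
      patient_id = config$patient_id,
      timestamp = format(Sys.time(), tz = "UTC"),
      readout_ppm = config$readout_ppm,
      alpha = config$alpha,
      voxel_accounting = list(
        head_voxels = n_head,
        masked_voxels = n_masked,
        b0_invalid = sum(z$mask) - sum(zc$mask),
        roi_total = as.list(roi_before),
        roi_after_exclusions = as.list(roi_after),
        roi_excluded = as.list(roi_before - roi_after),
        pairs_nonfinite_dropped = as.list(dropped),
        pairs_used = as.list(table(pairs$roi))
      ),
      tables = list(table1 = table1, table2 = table2),
      outputs = basename(c(written, file.path(out_dir, "manifest.json")))
    )
    mpath <- note(file.path(out_dir, "manifest.json"))
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Render a human-readable report of a pipeline run
#'
#' Writes `report.md` summarizing the run plus scatterplot images: the
#' voxelwise MTR_asym-ADC scatter per ROI and the biopsy cell-density
#' scatters against both contrasts, each with its least-squares line.
#' Empty ROIs are flagged in the report rather than omitted.
#'
#' @param out_dir Directory holding a completed [run_pipeline()] output.
#' @return Path of the report file, invisibly.
#' @export
render_report <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("no manifest.json in ", out_dir, "; run the pipeline first",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  t1 <- manifest$tables$table1
  t2 <- manifest$tables$table2
  samples <- utils::read.csv(file.path(out_dir, "fig5_points.csv"))
  mtr <- RNifti::readNifti(file.path(out_dir, "mtr_asym.nii.gz"))
  ds <- read_cest_dataset_safe(out_dir)

  lines <- c(
    sprintf("# NOE-CEST pipeline report (%s)", manifest$patient_id),
    "",
    sprintf("- package: noecest %s, seed %d", manifest$version,
            manifest$seed),
    sprintf("- MTR_asym readout: %.3f ppm; alpha = %g",
            manifest$readout_ppm, manifest$alpha),
    "",
    "## Voxel accounting",
    ""
  )
  va <- manifest$voxel_accounting
  lines <- c(lines,
             sprintf("- head voxels: %d; analyzable: %d; B0-invalid: %d",
                     va$head_voxels, va$masked_voxels, va$b0_invalid))
  for (roi in names(va$roi_total)) {
    lines <- c(lines, sprintf(
      "- %s: %d total, %d after exclusions, %d pairs used (%d non-finite dropped)",
      roi, va$roi_total[[roi]], va$roi_after_exclusions[[roi]],
      va$pairs_used[[roi]], va$pairs_nonfinite_dropped[[roi]]))
  }
  lines <- c(lines, "", "## Voxelwise MTR_asym vs ADC", "")
  for (i in seq_len(nrow(t1))) {
    if (t1$n_voxels[i] < 5 || is.na(t1$r_sp[i])) {
      lines <- c(lines, sprintf("- %s: EMPTY or too few voxels (n = %d)",
                                t1$roi[i], t1$n_voxels[i]))
    } else {
      lines <- c(lines, sprintf(
        "- %s: r_Sp = %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d -> %s",
        t1$roi[i], t1$r_sp[i], t1$ci_lo[i], t1$ci_hi[i], t1$p[i],
        t1$n_voxels[i], t1$class[i]))
    }
  }
  lines <- c(lines, "", "## Biopsy series vs cell density", "")
  for (i in seq_len(nrow(t2))) {
    lines <- c(lines, sprintf(
      "- %s: r_Sp = %.3f (p = %.3g, n = %d); OLS R^2 = %.3f (p = %.3g)",
      t2$contrast[i], t2$r_sp[i], t2$p[i], t2$n[i], t2$r_squared[i],
      t2$p_regression[i]))
  }

  figures <- character(0)
  if (!is.null(ds)) {
    pairs <- extract_pairs(array(as.numeric(mtr), dim = dim(mtr)[1:3]),
                           ds$adc,
                           apply_exclusions(roi_mask_set(
                             ds$roi_ce_t1_tumor, ds$roi_t2_edema,
                             ds$swi_exclusion, ds$roi_necrosis)))
    for (roi in unique(pairs$roi)) {
      sub <- pairs[pairs$roi == roi, ]
      if (nrow(sub) < 5) next
      f <- file.path(out_dir, sprintf("scatter_%s.png", roi))
      grDevices::png(f, width = 720, height = 540)
      plot(sub$mtr_asym_percent, sub$adc, pch = 16, cex = 0.4,
           col = grDevices::adjustcolor("steelblue", 0.4),
           xlab = "MTR_asym [%]", ylab = "ADC [1e-6 mm^2/s]",
           main = sprintf("%s (n = %d)", roi, nrow(sub)))
      graphics::abline(stats::lm(adc ~ mtr_asym_percent, data = sub),
                       col = "red", lwd = 2)
      grDevices::dev.off()
      figures <- c(figures, basename(f))
    }
  }
  ok <- is.finite(samples$cell_density_per_mm3)
  for (col in c("mtr_asym_mean_percent", "adc_mean")) {
    if (!col %in% names(samples)) next
    f <- file.path(out_dir, sprintf("biopsy_%s.png",
                                    sub("_mean.*", "", col)))
    grDevices::png(f, width = 600, height = 480)
    plot(samples[[col]][ok], samples$cell_density_per_mm3[ok], pch = 16,
         xlab = col, ylab = "cell density [cells/mm^3]",
         main = "Biopsy series")
    graphics::abline(stats::lm(samples$cell_density_per_mm3[ok] ~
                                 samples[[col]][ok]), col = "red")
    grDevices::dev.off()
    figures <- c(figures, basename(f))
  }
  lines <- c(lines, "", "## Files", "",
             paste0("- ", sort(unique(c(manifest$outputs, figures,
                                        "report.md")))))
  rpath <- file.path(out_dir, "report.md")
  writeLines(lines, rpath)
  invisible(rpath)
}

read_cest_dataset_safe <- function(out_dir) {
  ds_dir <- file.path(out_dir, "dataset")
  if (file.exists(file.path(ds_dir, "cest.nii.gz"))) {
    read_cest_dataset(ds_dir)
  } else {
    NULL
  }
}
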