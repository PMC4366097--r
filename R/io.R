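# NIfTI, CSV and sidecar I/O for the simulated datasets and result maps.

write_nifti_map <- function(arr, affine, path, datatype = "auto") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated CEST dataset to disk
#'
#' Writes the acquisition and phantom-derived inputs as NIfTI-1 files plus
#' plain-text sidecars: the 4D CEST stack with a JSON sidecar listing the
#' offset axis (ppm), the M0, ADC and label volumes, uint8 ROI/exclusion
#' masks, and the biopsy series as CSV.
#'
#' @param acq A [simulate_acquisition()] result.
#' @param phantom The [build_phantom()] result it came from.
#' @param dir Output directory (created if missing).
#' @param biopsies Optional [simulate_biopsy_set()] table.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cest_dataset <- function(acq, phantom, dir, biopsies = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- acq$affine
  paths <- c(
    cest = file.path(dir, "cest.nii.gz"),
    offsets = file.path(dir, "cest_offsets.json"),
    m0 = file.path(dir, "m0.nii.gz"),
    adc = file.path(dir, "adc.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    roi_ce = file.path(dir, "roi_ce_t1_tumor.nii.gz"),
    roi_edema = file.path(dir, "roi_t2_edema.nii.gz"),
    roi_necrosis = file.path(dir, "roi_necrosis.nii.gz"),
    swi = file.path(dir, "roi_swi_exclusion.nii.gz")
  )
  write_nifti_map(acq$sat, aff, paths[["cest"]])
  jsonlite::write_json(list(offsets_ppm = acq$offsets_ppm,
                            b1_uT = acq$acq$b1_uT,
                            n_pulses = acq$acq$n_pulses,
                            pulse_ms = acq$acq$pulse_ms,
                            interpulse_ms = acq$acq$interpulse_ms),
                       paths[["offsets"]], auto_unbox = TRUE, digits = NA)
  write_nifti_map(acq$m0, aff, paths[["m0"]])
  write_nifti_map(phantom$adc_map, aff, paths[["adc"]])
  write_nifti_map(phantom$label_map, aff, paths[["labels"]],
                  datatype = "uint8")
  lab <- phantom$label_map
  write_nifti_map((lab == 3L) * 1L, aff, paths[["roi_ce"]],
                  datatype = "uint8")
  write_nifti_map((lab == 2L) * 1L, aff, paths[["roi_edema"]],
                  datatype = "uint8")
  write_nifti_map((lab == 4L) * 1L, aff, paths[["roi_necrosis"]],
                  datatype = "uint8")
  write_nifti_map(phantom$swi_mask * 1L, aff, paths[["swi"]],
                  datatype = "uint8")
  if (!is.null(biopsies)) {
    paths <- c(paths, biopsies = file.path(dir, "biopsies.csv"))
    utils::write.csv(
      biopsies[, c("sample_id", "x_mm", "y_mm", "z_mm",
                   "distance_from_target_mm", "cell_density_per_mm3")],
      paths[["biopsies"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a CEST dataset written by [write_cest_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with a [zspectrum_volume()]-ready `sat` stack, `m0`,
#'   `offsets_ppm`, `affine`, `adc`, logical ROI masks and (if present) the
#'   biopsy table.
#' @export
read_cest_dataset <- function(dir) {
  need <- file.path(dir, c("cest.nii.gz", "cest_offsets.json", "m0.nii.gz"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cest <- RNifti::readNifti(file.path(dir, "cest.nii.gz"))
  side <- jsonlite::read_json(file.path(dir, "cest_offsets.json"),
                              simplifyVector = TRUE)
  m0 <- RNifti::readNifti(file.path(dir, "m0.nii.gz"))
  affine <- structure(RNifti::xform(cest), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  read_mask <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    array(RNifti::readNifti(p) > 0, dim = dim(m0))
  }
  out <- list(
    sat = array(as.numeric(cest), dim = dim(cest)),
    m0 = array(as.numeric(m0), dim = dim(m0)),
    offsets_ppm = as.numeric(side$offsets_ppm),
    affine = affine,
    adc = {
      p <- file.path(dir, "adc.nii.gz")
      if (file.exists(p)) {
        a <- RNifti::readNifti(p); array(as.numeric(a), dim = dim(a))
      } else NULL
    },
    roi_ce_t1_tumor = read_mask("roi_ce_t1_tumor.nii.gz"),
    roi_t2_edema = read_mask("roi_t2_edema.nii.gz"),
    roi_necrosis = read_mask("roi_necrosis.nii.gz"),
    swi_exclusion = read_mask("roi_swi_exclusion.nii.gz")
  )
  bp <- file.path(dir, "biopsies.csv")
  if (file.exists(bp)) out$biopsies <- utils::read.csv(bp)
  out
}
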