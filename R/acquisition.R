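#' Equidistant saturation-offset grid
#'
#' Builds the ordered list of saturation frequency offsets for a CEST
#' acquisition. The 7T protocol emulated by this package samples thirteen
#' equidistant offsets between -4 and +4 ppm, which places grid nodes at
#' +/- 10/3 ppm, the nodes nearest the nominal 3.3 ppm NOE readout.
#'
#' @param min_ppm Lowest offset (ppm, water = 0).
#' @param max_ppm Highest offset (ppm).
#' @param n Number of offsets (positive integer).
#' @return Numeric vector of `n` equidistant offsets from `min_ppm` to
#'   `max_ppm` inclusive, strictly increasing for `n > 1`.
#' @examples
#' make_offset_grid(-4, 4, 13)
#' @export
make_offset_grid <- function(min_ppm, max_ppm, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(min_ppm) || !is.numeric(max_ppm) ||
      length(min_ppm) != 1L || length(max_ppm) != 1L) {
    stop("`min_ppm` and `max_ppm` must be single numbers", call. = FALSE)
  }
  if (n > 1 && min_ppm >= max_ppm) {
    stop("`min_ppm` must be smaller than `max_ppm` when n > 1", call. = FALSE)
  }
  seq(min_ppm, max_ppm, length.out = n)
}

#' Saturation-train acquisition parameters
#'
#' Container for the pulsed-saturation settings of a CEST acquisition.
#' Defaults follow the emulated 7T protocol: 5 Gaussian pulses of 100 ms at a
#' train-average B1 of 0.7 uT with 100 ms interpulse delays, sampled on the
#' 13-point grid between -4 and +4 ppm. The pulse shape itself is never
#' simulated; `b1_uT`, `n_pulses` and the durations are carried as metadata
#' describing the acquisition the synthetic data stand in for.
#'
#' @param offsets_ppm Strictly increasing saturation offsets (ppm).
#' @param b1_uT Pulse-train-average saturation amplitude (microtesla).
#' @param n_pulses Number of saturation pulses.
#' @param pulse_ms Duration of one pulse (ms).
#' @param interpulse_ms Delay between consecutive pulses (ms).
#' @param noise_sigma Rician noise scale relative to the typical M0 signal
#'   (dimensionless; 0.01 = 1% noise).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(offsets_ppm = make_offset_grid(-4, 4, 13),
                               b1_uT = 0.7,
                               n_pulses = 5L,
                               pulse_ms = 100,
                               interpulse_ms = 100,
                               noise_sigma = 0.01) {
  if (length(offsets_ppm) < 1L || any(!is.finite(offsets_ppm)) ||
      is.unsorted(offsets_ppm, strictly = TRUE)) {
    stop("`offsets_ppm` must be finite and strictly increasing", call. = FALSE)
  }
  if (n_pulses < 1 || n_pulses != round(n_pulses)) {
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  }
  if (pulse_ms <= 0 || interpulse_ms < 0) {
    stop("durations must be positive (interpulse delay may be zero)",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(offsets_ppm = as.numeric(offsets_ppm),
         b1_uT = b1_uT,
         n_pulses = as.integer(n_pulses),
         pulse_ms = pulse_ms,
         interpulse_ms = interpulse_ms,
         noise_sigma = noise_sigma),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("CEST acquisition parameters\n")
  cat(sprintf("  offsets : %d from %.3g to %.3g ppm\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm)))
  cat(sprintf("  pulses  : %d x %g ms (B1 = %g uT), %g ms interpulse\n",
              x$n_pulses, x$pulse_ms, x$b1_uT, x$interpulse_ms))
  cat(sprintf("  t_sat   : %g ms effective\n", effective_saturation_ms(x)))
  cat(sprintf("  noise   : Rician, sigma = %g x M0\n", x$noise_sigma))
  invisible(x)
}

#' Effective saturation time of a pulse train
#'
#' Total duration over which saturation acts: the pulses plus the interpulse
#' gaps between them, `n * pulse + (n - 1) * interpulse`. For the default
#' protocol (5 x 100 ms pulses, 100 ms delays) this is 900 ms.
#'
#' @param n_pulses Number of pulses, or an [acquisition_params()] object (in
#'   which case the other arguments are taken from it).
#' @param pulse_ms Pulse duration (ms).
#' @param interpulse_ms Interpulse delay (ms).
#' @return Effective saturation time in ms.
#' @examples
#' effective_saturation_ms(5, 100, 100) # 900
#' @export
effective_saturation_ms <- function(n_pulses, pulse_ms = NULL,
                                    interpulse_ms = NULL) {
  if (inherits(n_pulses, "acquisition_params")) {
    acq <- n_pulses
    n_pulses <- acq$n_pulses
    pulse_ms <- acq$pulse_ms
    interpulse_ms <- acq$interpulse_ms
  }
  if (n_pulses < 1 || n_pulses != round(n_pulses)) {
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  }
  n_pulses * pulse_ms + (n_pulses - 1) * interpulse_ms
}
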