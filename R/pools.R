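#' Saturation pool specification
#'
#' One saturable proton pool contributing a Lorentzian dip to the Z-spectrum:
#' direct water saturation at 0 ppm, the exchange-relayed NOE of aliphatic
#' macromolecular protons upfield (here lumped at -3.3 ppm), or the amide
#' proton transfer (APT) pool at +3.5 ppm.
#'
#' @param center_ppm Chemical-shift offset of the pool (ppm, water = 0).
#' @param amplitude Peak saturation depth, a fraction of Z in `[0, 1)`.
#' @param width_ppm Full width at half maximum (ppm), > 0.
#' @return An object of class `pool_spec`.
#' @examples
#' pool_spec(0, 0.85, 3.0)     # direct water saturation (+ MT background)
#' pool_spec(-3.3, 0.08, 3.0)  # NOE pool
#' @export
pool_spec <- function(center_ppm, amplitude, width_ppm) {
  if (!is.finite(center_ppm)) stop("`center_ppm` must be finite", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0 || amplitude >= 1) {
    stop("`amplitude` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(width_ppm) || width_ppm <= 0) {
    stop("`width_ppm` must be > 0", call. = FALSE)
  }
  structure(list(center_ppm = center_ppm, amplitude = amplitude,
                 width_ppm = width_ppm),
            class = "pool_spec")
}

# Lorentzian absorption line parameterized by FWHM, unit peak at `center`.
lorentzian <- function(x, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / (hw2 + (x - center)^2)
}

#' Multi-pool Lorentzian Z-spectrum model
#'
#' Analytic generative model of the normalized Z-spectrum,
#' `Z(dw) = 1 - sum_k L_k(dw - b0_shift)`, where each `L_k` is a Lorentzian
#' with the pool's amplitude, center and width. A nonzero `b0_shift_ppm`
#' translates the whole spectrum, emulating static-field inhomogeneity. The
#' model is the ground-truth oracle for the processing chain; it makes no
#' attempt at Bloch-McConnell dynamics.
#'
#' @param offsets_ppm Saturation offsets at which to evaluate (ppm).
#' @param pools List of [pool_spec()] objects (may be empty).
#' @param b0_shift_ppm Water-center shift (ppm), default 0.
#' @return Numeric vector of Z values in `(0, 1]`, one per offset.
#' @examples
#' pools <- list(pool_spec(0, 0.85, 3.0), pool_spec(-3.3, 0.08, 3.0))
#' zspectrum_model(make_offset_grid(-4, 4, 13), pools)
#' @export
zspectrum_model <- function(offsets_ppm, pools, b0_shift_ppm = 0) {
  if (inherits(pools, "pool_spec")) pools <- list(pools)
  stopifnot(is.list(pools))
  for (p in pools) {
    if (!inherits(p, "pool_spec")) {
      p <- pool_spec(p$center_ppm, p$amplitude, p$width_ppm)
    }
  }
  z <- rep(1, length(offsets_ppm))
  for (p in pools) {
    z <- z - p$amplitude *
      lorentzian(offsets_ppm - b0_shift_ppm, p$center_ppm, p$width_ppm)
  }
  # Positivity guard: the dips are deepest at the (shifted) pool centers, so
  # checking there and at the requested offsets catches any configuration
  # that would drive Z non-positive.
  if (length(pools) > 0) {
    centers <- vapply(pools, `[[`, numeric(1), "center_ppm") + b0_shift_ppm
    zc <- rep(1, length(centers))
    for (p in pools) {
      zc <- zc - p$amplitude *
        lorentzian(centers - b0_shift_ppm, p$center_ppm, p$width_ppm)
    }
    if (any(c(z, zc) <= 0)) {
      stop("pool amplitudes drive Z non-positive; reduce amplitudes",
           call. = FALSE)
    }
  }
  z
}
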