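#' Default pump/probe frequency grid
#'
#' 35 pump and 85 probe points evenly spaced on 1550-1737 cm-1, matching the
#' amide I region after extraction (~2.2 cm-1 probe spacing, below the ~3 cm-1
#' probe resolution of a dual-array 2D-IR instrument).
#'
#' @param lo,hi region bounds in cm-1.
#' @param n_pump,n_probe number of grid points per axis.
#' @return List with `pump` and `probe` numeric vectors.
#' @export
default_grid <- function(lo = 1550, hi = 1737, n_pump = 35, n_probe = 85) {
  list(pump = seq(lo, hi, length.out = n_pump),
       probe = seq(lo, hi, length.out = n_probe))
}

#' Construct a 2D-IR spectrum object
#'
#' @param pump_axis,probe_axis strictly increasing wavenumber axes (cm-1).
#' @param amplitude matrix of dimension `length(pump_axis) x
#'   length(probe_axis)`; negative values are ground-state bleach, positive
#'   values excited-state absorption.
#' @param meta named list of acquisition metadata (protein_id, replicate,
#'   cycle, detector, waiting_time, day_offset).
#' @return Object of class `spectrum_2dir`.
#' @export
spectrum_2dir <- function(pump_axis, probe_axis, amplitude, meta = list()) {
  if (any(diff(pump_axis) <= 0) || any(diff(probe_axis) <= 0))
    stop("axes must be strictly increasing", call. = FALSE)
  amplitude <- as.matrix(amplitude)
  if (!all(dim(amplitude) == c(length(pump_axis), length(probe_axis))))
    stop("amplitude must be pump x probe", call. = FALSE)
  if (any(!is.finite(amplitude)))
    stop("amplitude must be finite everywhere", call. = FALSE)
  structure(list(pump_axis = pump_axis, probe_axis = probe_axis,
                 amplitude = amplitude, meta = meta),
            class = "spectrum_2dir")
}

#' @export
print.spectrum_2dir <- function(x, ...) {
  cat(sprintf("<spectrum_2dir> %d x %d, pump [%.0f, %.0f], probe [%.0f, %.0f] cm-1\n",
              length(x$pump_axis), length(x$probe_axis),
              min(x$pump_axis), max(x$pump_axis),
              min(x$probe_axis), max(x$probe_axis)))
  if (!is.null(x$meta$protein_id))
    cat("  protein:", x$meta$protein_id, "\n")
  invisible(x)
}

# 2D Gaussian elongated along the spectrum diagonal: coordinates are rotated
# 45 degrees so width_diag acts along pump = probe and width_antidiag across it.
gauss2d_diag <- function(pump, probe, c_pump, c_probe, w_diag, w_anti) {
  u <- outer(pump - c_pump, probe - c_probe, function(a, b) (a + b) / sqrt(2))
  v <- outer(pump - c_pump, probe - c_probe, function(a, b) (b - a) / sqrt(2))
  exp(-u^2 / (2 * w_diag^2) - v^2 / (2 * w_anti^2))
}

#' Render a 2D-IR spectrum from band components
#'
#' Each diagonal band contributes a negative (bleach) 2D Gaussian at
#' (pump = center, probe = center), elongated along the spectrum diagonal, and
#' a positive (excited-state absorption) Gaussian at
#' (pump = center, probe = partner_center). Cross components place the same
#' pair at (pump = cross_pump, probe = center). The total signal is scaled by
#' an exponential waiting-time decay and a per-detector gain; the probe axis
#' is displaced by a per-replicate calibration offset before gridding, and
#' zero-mean Gaussian noise with standard deviation `noise_sigma_rel *
#' max(abs(signal))` is added.
#'
#' @param bands list of band components from [bands_from_structure()].
#' @param grid grid definition from [default_grid()].
#' @param noise_sigma_rel relative noise level (>= 0).
#' @param tw waiting time in fs (decay referenced to 250 fs).
#' @param detector detector index (1-based; gains 1.00, 0.97, ...).
#' @param day_offset probe-axis calibration offset in cm-1.
#' @param seed integer seed for the noise draw.
#' @param t1_lifetime vibrational relaxation time constant in fs.
#' @param esa_relamp excited-state absorption amplitude relative to the bleach.
#' @param meta metadata list stored on the spectrum.
#' @return A [spectrum_2dir()] object.
#' @export
render_spectrum <- function(bands, grid = default_grid(), noise_sigma_rel = 0.02,
                            tw = 250, detector = 1L, day_offset = 0, seed = 1L,
                            t1_lifetime = 1000, esa_relamp = 0.85,
                            meta = list()) {
  if (!is.finite(noise_sigma_rel) || noise_sigma_rel < 0)
    stop("noise_sigma_rel must be finite and >= 0", call. = FALSE)
  if (!all(is.finite(c(tw, day_offset, t1_lifetime))))
    stop("non-finite rendering parameters", call. = FALSE)
  pump <- grid$pump
  probe <- grid$probe + day_offset   # recorded probe axis after recalibration
  sig <- matrix(0, length(pump), length(probe))
  for (b in bands) {
    c_pump <- if (is.finite(b$cross_pump)) b$cross_pump else b$center
    if (b$amplitude == 0) next
    sig <- sig -
      b$amplitude * gauss2d_diag(pump, probe, c_pump, b$center,
                                 b$width_diag, b$width_antidiag) +
      esa_relamp * b$amplitude *
        gauss2d_diag(pump, probe, c_pump, b$partner_center,
                     b$width_diag, b$width_antidiag)
  }
  gain <- c(1.00, 0.97)[((as.integer(detector) - 1L) %% 2L) + 1L]
  sig <- sig * gain * exp(-(tw - 250) / t1_lifetime)
  if (noise_sigma_rel > 0) {
    sigma <- noise_sigma_rel * max(abs(sig))
    if (sigma > 0) {
      set.seed(as.integer(seed))
      sig <- sig + matrix(rnorm(length(sig), sd = sigma),
                          nrow(sig), ncol(sig))
    }
  }
  meta$waiting_time <- tw
  meta$detector <- as.integer(detector)
  meta$day_offset <- day_offset
  spectrum_2dir(pump, probe, sig, meta)
}
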