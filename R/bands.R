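#' Default band-model parameters
#'
#' Parameters of the phenomenological amide I band model used to turn a
#' structure specification into spectral components. Frequencies are for
#' H2O-based solvent (upshifted ~10 cm-1 relative to D2O values).
#'
#' @return Named list of parameters:
#' \describe{
#'   \item{anharmonic_shift}{v=1->2 displacement below the fundamental (cm-1).}
#'   \item{helix_A_center}{A-symmetry helix mode for helices of ~10 residues (cm-1).}
#'   \item{helix_A_slope, helix_A_maxshift}{downshift per residue of the longest
#'     helix beyond 10 residues, and its cap (cm-1).}
#'   \item{helix_E_center, helix_E_relamp}{weak E-symmetry mode position and
#'     amplitude relative to the A mode.}
#'   \item{short_helix_centers}{positions of the scattered weak bands produced
#'     by helices shorter than 6 residues.}
#'   \item{sheet_perp_hi, sheet_perp_lo}{perpendicular sheet mode position at
#'     2 and at 8 mean strands (linear in between).}
#'   \item{sheet_para_center}{parallel (weak) sheet mode position.}
#'   \item{sheet_amp_gain}{amplitude enhancement per strand beyond 2.}
#'   \item{parallel_center}{single-band position used for parallel-registry sheet.}
#'   \item{coil_center, coil_width_diag}{random-coil band position and diagonal width.}
#'   \item{width_diag, width_antidiag}{default 2D Gaussian widths (cm-1).}
#'   \item{cross_coupling}{cross-peak amplitude as a fraction of the
#'     perpendicular-mode amplitude (antiparallel coupling).}
#'   \item{esa_relamp}{excited-state absorption amplitude relative to the bleach.}
#' }
#' @export
band_params <- function() {
  list(anharmonic_shift = 16,
       helix_A_center = 1660, helix_A_slope = 0.25, helix_A_maxshift = 8,
       helix_E_center = 1650, helix_E_relamp = 0.15,
       short_helix_centers = c(1640, 1660, 1680),
       sheet_perp_hi = 1642, sheet_perp_lo = 1628,
       sheet_para_center = 1676, sheet_amp_gain = 0.15,
       parallel_center = 1638,
       coil_center = 1652, coil_width_diag = 28,
       width_diag = 10, width_antidiag = 7,
       cross_coupling = 0.4, esa_relamp = 0.85)
}

band_component <- function(kind, center, amplitude, width_diag, width_antidiag,
                           anharmonic_shift = 16, cross_pump = NA_real_) {
  stopifnot(width_diag > 0, width_antidiag > 0, amplitude >= 0)
  list(kind = kind, center = center,
       partner_center = center - anharmonic_shift,
       amplitude = amplitude,
       width_diag = width_diag, width_antidiag = width_antidiag,
       cross_pump = cross_pump)
}

#' Derive amide I band components from a structure specification
#'
#' Maps secondary-structure content onto a list of phenomenological 2D band
#' components. Helical content produces an intense A-symmetry mode (downshifted
#' for long helices) and a weak E-symmetry mode; helices shorter than 6
#' residues instead contribute several weak bands scattered through the amide I
#' region. Antiparallel sheet produces the intense perpendicular mode (moving
#' down in frequency and up in amplitude with sheet size), the weak parallel
#' mode near 1676 cm-1, and the pair of off-diagonal coupling cross peaks that
#' complete the z-shaped pattern; parallel-registry sheet contributes a single
#' band. The non-helix, non-sheet remainder appears as a broad random-coil
#' band. Every diagonal component carries a v=1->2 partner displaced by the
#' anharmonic shift.
#'
#' @param spec a [structure_spec].
#' @param params band-model parameters, see [band_params()].
#' @return A list of band components (each a named list with fields `kind`,
#'   `center`, `partner_center`, `amplitude`, `width_diag`, `width_antidiag`,
#'   `cross_pump`).
#' @export
bands_from_structure <- function(spec, params = band_params()) {
  stopifnot(inherits(spec, "structure_spec"))
  p <- params
  bands <- list()

  ## helix contribution, split by helix-length regime
  hl <- spec$helix_lengths
  if (length(hl) && spec$frac_alpha > 0) {
    res_total <- sum(hl)
    frac_short <- sum(hl[hl < 6L]) / res_total * spec$frac_alpha
    frac_main <- spec$frac_alpha - frac_short
    if (frac_main > 0) {
      maxlen <- max(hl[hl >= 6L])
      shift <- if (maxlen > 15L)
        min(p$helix_A_maxshift, p$helix_A_slope * max(0, maxlen - 10)) else 0
      a_center <- p$helix_A_center - shift
      bands <- c(bands, list(
        band_component("helix_A", a_center, frac_main,
                       p$width_diag, p$width_antidiag, p$anharmonic_shift),
        band_component("helix_E", p$helix_E_center,
                       frac_main * p$helix_E_relamp,
                       p$width_diag, p$width_antidiag, p$anharmonic_shift)))
    }
    if (frac_short > 0) {
      for (ctr in p$short_helix_centers)
        bands <- c(bands, list(
          band_component("helix_E", ctr, frac_short / 3,
                         p$width_diag, p$width_antidiag, p$anharmonic_shift)))
    }
  }

  ## sheet contribution
  if (spec$frac_antiparallel > 0) {
    s <- min(8, max(2, spec$mean_sheet_strands))
    perp_center <- p$sheet_perp_hi +
      (p$sheet_perp_lo - p$sheet_perp_hi) * (s - 2) / 6
    gain <- 1 + p$sheet_amp_gain * (s - 2)
    amp_perp <- spec$frac_antiparallel * gain
    amp_para <- 0.25 * amp_perp
    bands <- c(bands, list(
      band_component("sheet_perp", perp_center, amp_perp,
                     p$width_diag, p$width_antidiag, p$anharmonic_shift),
      band_component("sheet_para", p$sheet_para_center, amp_para,
                     p$width_diag, p$width_antidiag, p$anharmonic_shift)))
    amp_cross <- p$cross_coupling * amp_perp
    bands <- c(bands, list(
      band_component("cross", perp_center, amp_cross,
                     p$width_diag, p$width_antidiag, p$anharmonic_shift,
                     cross_pump = p$sheet_para_center),
      band_component("cross", p$sheet_para_center, amp_cross,
                     p$width_diag, p$width_antidiag, p$anharmonic_shift,
                     cross_pump = perp_center)))
  }
  if (spec$frac_parallel > 0) {
    bands <- c(bands, list(
      band_component("sheet_perp", p$parallel_center, spec$frac_parallel,
                     p$width_diag, p$width_antidiag, p$anharmonic_shift)))
  }

  ## random-coil remainder (always present unless structure saturates)
  frac_coil <- max(0, 1 - spec$frac_alpha - spec$frac_beta)
  if (frac_coil > 0 || length(bands) == 0L) {
    bands <- c(bands, list(
      band_component("coil", p$coil_center, frac_coil,
                     p$coil_width_diag, p$width_antidiag, p$anharmonic_shift)))
  }
  bands
}
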