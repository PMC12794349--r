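#' Extract the amide I region of a spectrum
#'
#' Keeps the grid points of both axes that fall inside `[lo, hi]`, inclusive
#' at both ends, together with the corresponding amplitude submatrix. The
#' bounds are applied with a calibration tolerance (default 1.5 cm-1, half
#' the probe resolution) so that a probe axis displaced by a day-to-day
#' recalibration offset keeps its full pixel complement.
#'
#' @param spectrum a [spectrum_2dir()].
#' @param lo,hi region bounds in cm-1 (default 1550-1737, the amide I window).
#' @param tol calibration tolerance added on both sides (cm-1).
#' @return A cropped [spectrum_2dir()].
#' @export
extract_amide_region <- function(spectrum, lo = 1550, hi = 1737, tol = 1.5) {
  stopifnot(inherits(spectrum, "spectrum_2dir"))
  if (lo > hi) stop("invalid region: lo > hi", call. = FALSE)
  ip <- which(spectrum$pump_axis >= lo - tol & spectrum$pump_axis <= hi + tol)
  jp <- which(spectrum$probe_axis >= lo - tol & spectrum$probe_axis <= hi + tol)
  if (!length(ip) || !length(jp))
    stop("region does not intersect the spectrum axes", call. = FALSE)
  spectrum_2dir(spectrum$pump_axis[ip], spectrum$probe_axis[jp],
                spectrum$amplitude[ip, jp, drop = FALSE], spectrum$meta)
}

#' Align probe axes across a library by per-pixel binning
#'
#' Probe recalibration between acquisition days leaves small wavenumber
#' discrepancies (within the instrument resolution) between spectra at the
#' same probe pixel. Binning replaces every spectrum's probe axis by the
#' per-pixel-index mean across the library; amplitudes are untouched.
#' Idempotent.
#'
#' @param library a `spectral_library`.
#' @param max_spread warn if the per-pixel wavenumber spread exceeds this
#'   (cm-1); binning is still applied.
#' @return The library with a common probe axis.
#' @export
bin_probe_axes <- function(library, max_spread = 3) {
  stopifnot(inherits(library, "spectral_library"))
  n_probe <- vapply(library$spectra, function(s) length(s$probe_axis), 1L)
  n_pump <- vapply(library$spectra, function(s) length(s$pump_axis), 1L)
  if (length(unique(n_probe)) != 1L || length(unique(n_pump)) != 1L)
    stop("spectra disagree in pixel counts; cannot bin", call. = FALSE)
  axes <- do.call(rbind, lapply(library$spectra, `[[`, "probe_axis"))
  spread <- apply(axes, 2L, function(v) diff(range(v)))
  if (any(spread > max_spread))
    warning(sprintf("probe-axis spread up to %.2f cm-1 exceeds %.2f; binning anyway",
                    max(spread), max_spread))
  common <- colMeans(axes)
  library$spectra <- lapply(library$spectra, function(s) {
    s$probe_axis <- common
    s
  })
  library
}

#' Vectorize a 2D-IR spectrum
#'
#' Concatenates probe-direction slices in ascending pump order (pump-major),
#' so element `(i-1) * n_probe + j` is the amplitude at pump i, probe j. The
#' default 35 x 85 amide I grid yields a 2975-dimensional feature vector.
#'
#' @param spectrum a region-extracted [spectrum_2dir()].
#' @return List with `row` (numeric vector) and `coords` (data frame with
#'   `pump_cm1`, `probe_cm1` per feature).
#' @export
vectorize <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_2dir"))
  row <- as.numeric(t(spectrum$amplitude))   # pump-major concatenation
  coords <- data.frame(
    pump_cm1 = rep(spectrum$pump_axis, each = length(spectrum$probe_axis)),
    probe_cm1 = rep(spectrum$probe_axis, times = length(spectrum$pump_axis)))
  list(row = row, coords = coords)
}

#' Extract the diagonal slice of a 2D-IR spectrum
#'
#' For each pump frequency, takes the amplitude at the probe pixel nearest
#' that pump frequency (the pump and probe grids differ in spacing), giving
#' one value per pump point ordered by pump frequency — the 2D analogue of
#' the linear absorption band.
#'
#' @param spectrum a region-extracted [spectrum_2dir()].
#' @return List with `row` (length = pump pixel count) and `coords`.
#' @export
extract_diagonal <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_2dir"))
  j <- vapply(spectrum$pump_axis,
              function(p) which.min(abs(spectrum$probe_axis - p)), 1L)
  row <- spectrum$amplitude[cbind(seq_along(spectrum$pump_axis), j)]
  coords <- data.frame(pump_cm1 = spectrum$pump_axis,
                       probe_cm1 = spectrum$probe_axis[j])
  list(row = row, coords = coords)
}

#' Assemble the N x M analysis feature frame
#'
#' Converts a (binned) spectral library into the data frame consumed by the
#' machine-learning pipelines: N spectra by M features, where M is the full
#' vectorised spectrum (2975 on the default grid) or the diagonal slice (35).
#' Rows are sorted into a stable (protein, replicate, cycle, waiting_time,
#' detector) order independent of storage order.
#'
#' @param library a `spectral_library` with a common probe axis.
#' @param mode `"full"` or `"diagonal"`.
#' @return Object of class `feature_frame`: list with `matrix` (N x M),
#'   `feature_coords` (data frame, one row per column), `row_meta`
#'   (data frame with protein_id, replicate, cycle, waiting_time, detector)
#'   and `group_of` (character vector, protein per row).
#' @export
assemble_frame <- function(library, mode = c("full", "diagonal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "spectral_library"))
  meta <- do.call(rbind, lapply(library$spectra, function(s)
    data.frame(protein_id = s$meta$protein_id,
               replicate = s$meta$replicate,
               cycle = s$meta$cycle,
               waiting_time = s$meta$waiting_time,
               detector = s$meta$detector)))
  ord <- order(meta$protein_id, meta$replicate, meta$cycle,
               meta$waiting_time, meta$detector)
  if (anyDuplicated(meta[ord, ]))
    stop("duplicate (protein, replicate, cycle, waiting_time, detector) tuples",
         call. = FALSE)
  extract <- if (mode == "full") vectorize else extract_diagonal
  first <- extract(library$spectra[[ord[1]]])
  # plain row extraction (coords are shared across the binned library)
  row_of <- if (mode == "full") {
    function(s) as.numeric(t(s$amplitude))
  } else {
    function(s) {
      j <- vapply(s$pump_axis, function(p) which.min(abs(s$probe_axis - p)), 1L)
      s$amplitude[cbind(seq_along(s$pump_axis), j)]
    }
  }
  mat <- matrix(NA_real_, length(ord), length(first$row))
  for (k in seq_along(ord))
    mat[k, ] <- row_of(library$spectra[[ord[k]]])
  if (anyNA(mat)) stop("missing values in feature frame", call. = FALSE)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(matrix = mat, feature_coords = first$coords,
                 row_meta = meta, group_of = meta$protein_id),
            class = "feature_frame")
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("<feature_frame> %d spectra x %d features, %d proteins\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$group_of))))
  invisible(x)
}

#' Export a feature frame as CSV
#'
#' Metadata columns first, then one column per feature labelled
#' `"<pump>|<probe>"` in cm-1.
#'
#' @param frame a `feature_frame`.
#' @param path output path.
#' @export
write_frame_csv <- function(frame, path) {
  labels <- sprintf("%.2f|%.2f", frame$feature_coords$pump_cm1,
                    frame$feature_coords$probe_cm1)
  df <- cbind(frame$row_meta, as.data.frame(frame$matrix))
  names(df) <- c(names(frame$row_meta), labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
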