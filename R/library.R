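#' Acquisition plan for a synthetic spectral library
#'
#' Describes the measurement accounting used when expanding one protein into
#' repeated spectra: measurement cycles, waiting times, detectors and
#' replicate transmission cells. The defaults reproduce the accounting of the
#' emulated experimental library: 3 cycles x 11 waiting times (250-300 fs in
#' 5 fs steps) x 2 detectors, in triplicate, which gives 198 spectra per
#' protein; `replicate_overrides` reduces selected proteins (scarce-sample
#' proteins measured in duplicate or singly).
#'
#' @param n_cycles measurement cycles per replicate.
#' @param waiting_times pump-probe waiting times in fs.
#' @param n_detectors number of detectors.
#' @param n_replicates_default replicate cells per protein.
#' @param replicate_overrides named integer vector, protein_id -> replicates.
#' @param noise_sigma_rel relative amplitude noise added per spectrum.
#' @param calib_jitter probe-axis calibration jitter, drawn uniformly in
#'   +/- this value (cm-1) once per replicate (one "day" per replicate).
#' @param t1_lifetime vibrational lifetime for the waiting-time decay (fs).
#' @return Object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(n_cycles = 3L,
                             waiting_times = seq(250, 300, by = 5),
                             n_detectors = 2L,
                             n_replicates_default = 3L,
                             replicate_overrides = integer(0),
                             noise_sigma_rel = 0.02,
                             calib_jitter = 1.5,
                             t1_lifetime = 1000) {
  stopifnot(n_cycles >= 1, length(waiting_times) >= 1, n_detectors >= 1,
            n_replicates_default >= 1, noise_sigma_rel >= 0, calib_jitter >= 0,
            t1_lifetime > 0)
  if (length(replicate_overrides) &&
      (is.null(names(replicate_overrides)) || any(!nzchar(names(replicate_overrides)))))
    stop("replicate_overrides must be a named vector", call. = FALSE)
  structure(list(n_cycles = as.integer(n_cycles),
                 waiting_times = as.numeric(waiting_times),
                 n_detectors = as.integer(n_detectors),
                 n_replicates_default = as.integer(n_replicates_default),
                 replicate_overrides = replicate_overrides,
                 noise_sigma_rel = noise_sigma_rel,
                 calib_jitter = calib_jitter,
                 t1_lifetime = t1_lifetime),
            class = "acquisition_plan")
}

#' Expected spectrum count under a plan
#'
#' @param plan an [acquisition_plan()].
#' @param specs list of [structure_spec] (for replicate overrides).
#' @return Integer total spectrum count.
#' @export
plan_spectrum_count <- function(plan, specs) {
  per_rep <- plan$n_cycles * length(plan$waiting_times) * plan$n_detectors
  reps <- vapply(specs, function(s) {
    r <- plan$replicate_overrides[s$protein_id]
    if (length(r) == 1L && !is.na(r)) as.integer(r) else plan$n_replicates_default
  }, 1L)
  as.integer(sum(reps * per_rep))
}

#' Build a synthetic 2D-IR spectral library
#'
#' Expands each structure specification into its full set of repeated spectra
#' (replicates x cycles x waiting times x detectors). One probe-calibration
#' offset is drawn per replicate; per-spectrum noise and all random draws are
#' governed by `seed`, so identical inputs give bit-identical libraries.
#'
#' @param specs non-empty list of [structure_spec].
#' @param plan an [acquisition_plan()].
#' @param seed integer seed.
#' @param grid frequency grid, see [default_grid()].
#' @param params band-model parameters, see [band_params()].
#' @return Object of class `spectral_library`: list with `spectra` (list of
#'   [spectrum_2dir()]), `structures` (named list of [structure_spec]) and
#'   `groups` (named list: protein_id -> spectrum indices).
#' @export
build_library <- function(specs, plan = acquisition_plan(), seed = 1L,
                          grid = default_grid(), params = band_params()) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  ids <- vapply(specs, `[[`, "", "protein_id")
  if (anyDuplicated(ids)) stop("duplicate protein_id", call. = FALSE)
  unknown <- setdiff(names(plan$replicate_overrides), ids)
  if (length(unknown))
    stop("replicate_overrides name unknown proteins: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  set.seed(as.integer(seed))
  spectra <- list()
  groups <- stats::setNames(vector("list", length(ids)), ids)
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    bands <- bands_from_structure(spec, params)
    r <- plan$replicate_overrides[spec$protein_id]
    n_rep <- if (length(r) == 1L && !is.na(r)) as.integer(r) else plan$n_replicates_default
    idx <- integer(0)
    for (rep_i in seq_len(n_rep)) {
      day_offset <- stats::runif(1, -plan$calib_jitter, plan$calib_jitter)
      for (cyc in seq_len(plan$n_cycles))
        for (tw in plan$waiting_times)
          for (det in seq_len(plan$n_detectors)) {
            noise_seed <- sample.int(.Machine$integer.max, 1L)
            sp <- render_spectrum(
              bands, grid = grid,
              noise_sigma_rel = plan$noise_sigma_rel,
              tw = tw, detector = det, day_offset = day_offset,
              seed = noise_seed, t1_lifetime = plan$t1_lifetime,
              esa_relamp = params$esa_relamp,
              meta = list(protein_id = spec$protein_id,
                          replicate = rep_i, cycle = cyc))
            spectra[[length(spectra) + 1L]] <- sp
            idx <- c(idx, length(spectra))
          }
    }
    groups[[spec$protein_id]] <- idx
  }
  structure(list(spectra = spectra,
                 structures = stats::setNames(specs, ids),
                 groups = groups),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d spectra, %d proteins\n",
              length(x$spectra), length(x$structures)))
  invisible(x)
}

#' Write / read a spectral library directory
#'
#' A library directory holds `manifest.json` (structure table, group map and
#' per-spectrum metadata) plus one delimited matrix file per spectrum with
#' `#pump:` and `#probe:` header lines listing the axes.
#'
#' @param library a `spectral_library`.
#' @param dir directory path (created if absent).
#' @return `read_library` returns a `spectral_library`.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "spectral_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("spectrum_%05d.tsv", seq_along(library$spectra))
  for (i in seq_along(library$spectra)) {
    sp <- library$spectra[[i]]
    con <- file(file.path(dir, files[i]), "w")
    writeLines(paste0("#pump: ", paste(format(sp$pump_axis, digits = 12), collapse = "\t")), con)
    writeLines(paste0("#probe: ", paste(format(sp$probe_axis, digits = 12), collapse = "\t")), con)
    utils::write.table(sp$amplitude, con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  meta <- lapply(seq_along(library$spectra), function(i) {
    m <- library$spectra[[i]]$meta
    c(list(file = files[i]), m)
  })
  structures <- lapply(unname(library$structures), function(s)
    s[c("protein_id", "frac_alpha", "frac_beta", "frac_parallel",
        "frac_antiparallel", "helix_lengths", "n_residues", "mean_sheet_strands")])
  jsonlite::write_json(
    list(structures = structures, groups = library$groups, spectra = meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  specs <- lapply(man$structures, function(s)
    structure_spec(s$protein_id, s$frac_alpha, s$frac_beta, s$frac_parallel,
                   s$frac_antiparallel, unlist(s$helix_lengths), s$n_residues,
                   s$mean_sheet_strands))
  ids <- vapply(specs, `[[`, "", "protein_id")
  spectra <- lapply(man$spectra, function(m) {
    path <- file.path(dir, m$file)
    hdr <- readLines(path, n = 2L)
    pump <- as.numeric(strsplit(sub("^#pump: ", "", hdr[1]), "\t")[[1]])
    probe <- as.numeric(strsplit(sub("^#probe: ", "", hdr[2]), "\t")[[1]])
    amp <- as.matrix(utils::read.table(path, sep = "\t", skip = 2L))
    dimnames(amp) <- NULL
    m$file <- NULL
    spectrum_2dir(pump, probe, amp, lapply(m, function(v) v))
  })
  groups <- lapply(man$groups, function(g) as.integer(unlist(g)))
  structure(list(spectra = spectra,
                 structures = stats::setNames(specs, ids),
                 groups = groups[ids]),
            class = "spectral_library")
}
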