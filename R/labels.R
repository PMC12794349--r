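#' Assign a structural class from helix and sheet fractions
#'
#' Three-way classification of a protein by its secondary-structure balance:
#' `alpha_enriched` when `frac_alpha - frac_beta >= threshold`,
#' `beta_enriched` when `frac_alpha - frac_beta <= -threshold`, and `mixed`
#' otherwise. Boundary values fall into the enriched classes. The threshold
#' (default 0.2) is exposed because the symmetric reading of the rule is a
#' deliberate choice: a one-sided reading would leave the mixed class empty.
#'
#' @param frac_alpha,frac_beta fractions in \[0, 1\].
#' @param threshold class threshold on the alpha-beta difference.
#' @return One of `"alpha_enriched"`, `"mixed"`, `"beta_enriched"`.
#' @examples
#' assign_class(0.70, 0.05)  # alpha_enriched
#' assign_class(0.30, 0.25)  # mixed
#' @export
assign_class <- function(frac_alpha, frac_beta, threshold = 0.2) {
  if (any(!is.finite(c(frac_alpha, frac_beta))) ||
      frac_alpha < 0 || frac_alpha > 1 || frac_beta < 0 || frac_beta > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  d <- frac_alpha - frac_beta
  if (d >= threshold) "alpha_enriched"
  else if (d <= -threshold) "beta_enriched"
  else "mixed"
}

#' Assign a helix-length class
#'
#' `long_helices` if any helix is strictly longer than `cutoff` residues
#' (default 15), else `short_helices`; a protein with no helices is short.
#'
#' @param helix_lengths integer vector of helix lengths (residues).
#' @param cutoff length cutoff in residues.
#' @return `"long_helices"` or `"short_helices"`.
#' @export
assign_helix_length_class <- function(helix_lengths, cutoff = 15L) {
  if (length(helix_lengths) && any(helix_lengths < 0))
    stop("helix lengths must be non-negative", call. = FALSE)
  m <- if (length(helix_lengths)) max(helix_lengths) else 0L
  if (m > cutoff) "long_helices" else "short_helices"
}

#' Attach machine-learning target labels to a feature frame
#'
#' Appends per-row label columns to `frame$row_meta` according to `task`:
#' \describe{
#'   \item{class}{structural class via [assign_class()].}
#'   \item{fractions}{`alpha_pct` and `beta_pct` (0-100 scale).}
#'   \item{helix_length}{short/long helix class via [assign_helix_length_class()].}
#'   \item{helix_count}{`n_helices` (integer) plus `alpha_pct` for chaining.}
#'   \item{sheet_registry}{`parallel_pct` and `antiparallel_pct` (0-100).}
#' }
#' Regression targets are expressed in percent, matching the scale on which
#' prediction errors are quoted.
#'
#' @param frame a `feature_frame`.
#' @param structures named list protein_id -> [structure_spec] (as in a
#'   `spectral_library`).
#' @param task one of `"class"`, `"fractions"`, `"helix_length"`,
#'   `"helix_count"`, `"sheet_registry"`.
#' @param threshold class threshold, passed to [assign_class()].
#' @return The frame with label columns appended to `row_meta` and a
#'   `label_cols` attribute naming them.
#' @export
label_frame <- function(frame, structures,
                        task = c("class", "fractions", "helix_length",
                                 "helix_count", "sheet_registry"),
                        threshold = 0.2) {
  task <- match.arg(task)
  stopifnot(inherits(frame, "feature_frame"))
  missing <- setdiff(unique(frame$group_of), names(structures))
  if (length(missing))
    stop("no structure record for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  per_protein <- lapply(structures, function(s) {
    switch(task,
      class = data.frame(class = assign_class(s$frac_alpha, s$frac_beta,
                                              threshold)),
      fractions = data.frame(alpha_pct = 100 * s$frac_alpha,
                             beta_pct = 100 * s$frac_beta),
      helix_length = data.frame(
        helix_length_class = assign_helix_length_class(s$helix_lengths)),
      helix_count = data.frame(n_helices = length(s$helix_lengths),
                               alpha_pct = 100 * s$frac_alpha),
      sheet_registry = data.frame(parallel_pct = 100 * s$frac_parallel,
                                  antiparallel_pct = 100 * s$frac_antiparallel))
  })
  lab <- do.call(rbind, per_protein[frame$group_of])
  rownames(lab) <- NULL
  frame$row_meta <- cbind(frame$row_meta, lab)
  attr(frame, "label_cols") <- names(lab)
  frame
}

#' Export the per-protein label table
#'
#' One row per protein with class assignment, percentage targets and helix
#' summaries.
#'
#' @param structures named list of [structure_spec].
#' @param path CSV output path.
#' @param threshold class threshold.
#' @return The table, invisibly (also written to `path` if non-NULL).
#' @export
write_label_table <- function(structures, path = NULL, threshold = 0.2) {
  df <- do.call(rbind, lapply(unname(structures), function(s) data.frame(
    protein_id = s$protein_id,
    class = assign_class(s$frac_alpha, s$frac_beta, threshold),
    frac_alpha_pct = 100 * s$frac_alpha,
    frac_beta_pct = 100 * s$frac_beta,
    n_helices = length(s$helix_lengths),
    max_helix_len = if (length(s$helix_lengths)) max(s$helix_lengths) else 0L,
    frac_parallel_pct = 100 * s$frac_parallel,
    frac_antiparallel_pct = 100 * s$frac_antiparallel)))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
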