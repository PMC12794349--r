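#' Construct a protein secondary-structure specification
#'
#' A `structure_spec` records the per-protein ground truth used to label
#' synthetic spectra: DSSP-style fractions of alpha-helix and beta-sheet,
#' the parallel/antiparallel split of the sheet content, the list of helix
#' lengths and the residue count, plus the mean number of strands per sheet
#' (which controls the perpendicular sheet mode's position and amplitude).
#'
#' @param protein_id character scalar, unique protein identifier.
#' @param frac_alpha fraction of residues in alpha-helix, in \[0, 1\].
#' @param frac_beta fraction of residues in beta-sheet, in \[0, 1\];
#'   `frac_alpha + frac_beta` must not exceed 1.
#' @param frac_parallel,frac_antiparallel split of `frac_beta` into parallel
#'   and antiparallel registry; must sum to `frac_beta`.
#' @param helix_lengths integer vector of per-helix residue counts; their sum
#'   must equal `round(frac_alpha * n_residues)` within one residue.
#' @param n_residues total residue count (positive integer).
#' @param mean_sheet_strands mean number of strands per beta-sheet (>= 1).
#' @return An object of class `structure_spec` (a named list).
#' @export
structure_spec <- function(protein_id, frac_alpha, frac_beta,
                           frac_parallel, frac_antiparallel,
                           helix_lengths, n_residues, mean_sheet_strands) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  fr <- c(frac_alpha, frac_beta, frac_parallel, frac_antiparallel)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all fractions must be finite and within [0, 1]", call. = FALSE)
  if (frac_alpha + frac_beta > 1 + 1e-9)
    stop("frac_alpha + frac_beta must not exceed 1", call. = FALSE)
  if (abs(frac_parallel + frac_antiparallel - frac_beta) > 1e-9)
    stop("frac_parallel + frac_antiparallel must equal frac_beta", call. = FALSE)
  helix_lengths <- as.integer(helix_lengths)
  if (any(helix_lengths < 0)) stop("helix lengths must be non-negative", call. = FALSE)
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1L, mean_sheet_strands >= 1)
  if (abs(sum(helix_lengths) - frac_alpha * n_residues) > 1)
    stop("sum(helix_lengths) must match frac_alpha * n_residues within 1 residue",
         call. = FALSE)
  structure(
    list(protein_id = protein_id,
         frac_alpha = frac_alpha, frac_beta = frac_beta,
         frac_parallel = frac_parallel, frac_antiparallel = frac_antiparallel,
         helix_lengths = helix_lengths, n_residues = n_residues,
         mean_sheet_strands = mean_sheet_strands),
    class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  cat(sprintf("<structure_spec> %s: alpha %.1f%%, beta %.1f%% (par %.1f%% / anti %.1f%%), %d residues, %d helices\n",
              x$protein_id, 100 * x$frac_alpha, 100 * x$frac_beta,
              100 * x$frac_parallel, 100 * x$frac_antiparallel,
              x$n_residues, length(x$helix_lengths)))
  invisible(x)
}

# Partition `total` helical residues into individual helix lengths.
# `long` selects the long-helix regime (lengths up to ~33 residues, at least
# one > 15) versus the short regime (all <= 15, some < 6).
draw_helix_lengths <- function(total, long) {
  if (total < 4L) return(if (total > 0L) as.integer(total) else integer(0))
  lengths <- integer(0)
  remaining <- total
  first <- TRUE
  while (remaining > 0L) {
    if (long && first) {
      len <- sample(16:33, 1L)              # guarantee one >15-residue helix
    } else if (long) {
      len <- sample(5:22, 1L)
    } else {
      len <- sample(4:15, 1L)
    }
    len <- min(len, remaining)
    # avoid a trailing 1-2 residue stub: fold it into the last helix
    if (remaining - len <= 3L) len <- remaining
    if (!long) len <- min(len, 15L)
    lengths <- c(lengths, len)
    remaining <- remaining - len
    first <- FALSE
  }
  # short regime may exceed 15 only via the stub fold; split if it happened
  if (!long && any(lengths > 15L)) {
    i <- which(lengths > 15L)
    extra <- lengths[i] - 12L
    lengths[i] <- 12L
    lengths <- c(lengths, extra)
  }
  as.integer(lengths)
}

#' Sample a set of synthetic protein structure specifications
#'
#' Draws `n_proteins` structure specifications emulating the composition of
#' a curated protein library: alpha-helix fractions span 0-0.71 and
#' beta-sheet fractions 0-0.48, the two are negatively correlated across the
#' set, roughly half the sheet-containing proteins carry no parallel sheet,
#' and helix lengths cover both the short (<= 15 residues) and long (> 15)
#' regimes. Class composition follows the 8:16:11
#' (alpha-enriched : mixed : beta-enriched) proportions of the emulated
#' library, so all three structural classes are populated for n >= 6.
#'
#' @param n_proteins number of proteins (>= 3).
#' @param seed integer seed; identical seeds give identical sets.
#' @return A list of [structure_spec] objects.
#' @examples
#' specs <- sample_structures(6, seed = 1)
#' sapply(specs, function(s) s$frac_alpha)
#' @export
sample_structures <- function(n_proteins, seed) {
  if (!is.numeric(n_proteins) || n_proteins < 3)
    stop("n_proteins must be at least 3", call. = FALSE)
  n_proteins <- as.integer(n_proteins)
  set.seed(as.integer(seed))

  # class quotas proportional to the emulated library (8/16/11 of 35)
  n_alpha <- max(1L, round(n_proteins * 8 / 35))
  n_beta  <- max(1L, round(n_proteins * 11 / 35))
  n_mixed <- n_proteins - n_alpha - n_beta
  if (n_mixed < 1L) { n_mixed <- 1L; n_beta <- n_proteins - n_alpha - n_mixed }
  classes <- c(rep("alpha", n_alpha), rep("mixed", n_mixed), rep("beta", n_beta))

  specs <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    cls <- classes[i]
    if (cls == "alpha") {                       # alpha - beta >= 0.2
      a <- runif(1, 0.32, 0.71)
      b <- runif(1, 0, min(0.30, a - 0.22))
    } else if (cls == "beta") {                 # beta - alpha >= 0.2
      b <- runif(1, 0.25, 0.48)
      a <- runif(1, 0, b - 0.22)
    } else {                                    # |alpha - beta| < 0.2
      a <- runif(1, 0.05, 0.50)
      b <- a + runif(1, -0.17, 0.17)
      b <- min(max(b, 0), 0.48, 1 - a)
    }
    n_res <- sample(90:450, 1L)
    helical <- as.integer(floor(a * n_res))  # floor keeps frac_alpha within its sampling bound
    long_regime <- (i %% 2L == 0L) && helical >= 16L
    hl <- draw_helix_lengths(helical, long_regime)
    a_exact <- sum(hl) / n_res
    # parallel sheet absent in ~half the set; otherwise a minor share
    if (b > 0 && runif(1) > 0.5) {
      par <- min(runif(1, 0.15, 0.4) * b, 0.131)
    } else par <- 0
    strands <- min(8, max(2, 2 + 12 * b * runif(1, 0.7, 1.3)))
    specs[[i]] <- structure_spec(
      protein_id = sprintf("protein_%02d", i),
      frac_alpha = a_exact, frac_beta = b,
      frac_parallel = par, frac_antiparallel = b - par,
      helix_lengths = hl, n_residues = n_res,
      mean_sheet_strands = strands)
  }
  specs
}

#' Write / read a structure specification table
#'
#' Round-trips a list of [structure_spec] objects through a delimited text
#' table with one row per protein. Helix lengths are semicolon-joined.
#'
#' @param specs list of [structure_spec].
#' @param path file path (CSV).
#' @return `read_structure_table` returns a list of [structure_spec].
#' @export
write_structure_table <- function(specs, path) {
  df <- data.frame(
    protein_id = vapply(specs, `[[`, "", "protein_id"),
    frac_alpha = vapply(specs, `[[`, 0, "frac_alpha"),
    frac_beta = vapply(specs, `[[`, 0, "frac_beta"),
    frac_parallel = vapply(specs, `[[`, 0, "frac_parallel"),
    frac_antiparallel = vapply(specs, `[[`, 0, "frac_antiparallel"),
    helix_lengths = vapply(specs, function(s) paste(s$helix_lengths, collapse = ";"), ""),
    n_residues = vapply(specs, `[[`, 1L, "n_residues"),
    mean_sheet_strands = vapply(specs, `[[`, 0, "mean_sheet_strands"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_table
#' @export
read_structure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("protein_id", "frac_alpha", "frac_beta", "frac_parallel",
              "frac_antiparallel", "helix_lengths", "n_residues",
              "mean_sheet_strands")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("structure table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    hl <- df$helix_lengths[i]
    hl <- if (is.na(hl) || !nzchar(hl)) integer(0) else
      as.integer(strsplit(hl, ";", fixed = TRUE)[[1]])
    structure_spec(df$protein_id[i], df$frac_alpha[i], df$frac_beta[i],
                   df$frac_parallel[i], df$frac_antiparallel[i],
                   hl, df$n_residues[i], df$mean_sheet_strands[i])
  })
}
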