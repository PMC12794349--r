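# Shared fixture builders. Everything is generated in code at test time.

# A minimal plan: one spectrum per replicate combination.
unit_plan <- function(...) {
  acquisition_plan(n_cycles = 1L, waiting_times = 250, n_detectors = 1L,
                   n_replicates_default = 1L, ...)
}

# Reduced plan used for ML-level tests: 9 spectra per protein.
reduced_plan <- function(...) {
  acquisition_plan(n_cycles = 1L, waiting_times = c(250, 275, 300),
                   n_detectors = 1L, n_replicates_default = 3L, ...)
}

# Hand-built structure spec with exact fractions.
mk_spec <- function(id, alpha, beta, par = 0, helix_lengths = NULL,
                    n_res = 200L, strands = 4) {
  if (is.null(helix_lengths)) {
    total <- floor(alpha * n_res)
    helix_lengths <- if (total > 0) {
      n_h <- max(1L, total %/% 12L)
      lens <- rep(total %/% n_h, n_h)
      lens[1] <- lens[1] + total - sum(lens)
      lens
    } else integer(0)
  }
  structure_spec(id, sum(helix_lengths) / n_res, beta, par, beta - par,
                 helix_lengths, n_res, strands)
}

# Six proteins with widely separated class archetypes (two per class);
# spectra of the same class are near-identical, so a noiseless library built
# from them is separable by construction.
archetype_specs <- function() {
  list(
    mk_spec("alpha_a", 0.65, 0.02, helix_lengths = c(20, 20, 20, 20, 20, 20, 10)),
    mk_spec("alpha_b", 0.62, 0.04, helix_lengths = c(18, 18, 18, 18, 18, 18, 16)),
    mk_spec("mixed_a", 0.30, 0.30, strands = 5),
    mk_spec("mixed_b", 0.28, 0.32, strands = 5),
    mk_spec("beta_a", 0.05, 0.45, strands = 6),
    mk_spec("beta_b", 0.04, 0.42, strands = 6))
}

# Small labelled frame for pipeline-level tests.
small_labelled_frame <- function(task = "class", noise = 0.02, seed = 11,
                                 specs = archetype_specs()) {
  plan <- reduced_plan(noise_sigma_rel = noise)
  lib <- bin_probe_axes(build_library(specs, plan, seed = seed))
  label_frame(assemble_frame(lib, "full"), lib$structures, task)
}
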