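#!/usr/bin/env Rscript
# Stage 1: sample the 35-protein structure set and build the synthetic
# 2D-IR library used by all downstream analyses.
#
# The full experimental-style accounting (3 cycles x 11 waiting times x
# 2 detectors, triplicate, with one duplicate- and one single-measured
# protein) is verified here at full scale; the analysis library itself is
# built under a reduced plan (1 cycle x 3 waiting times x 1 detector,
# triplicate -> 9 spectra per protein) that keeps every later stage at desk
# scale without changing the protein-level structure of the data.

suppressPackageStartupMessages(library(amide2d))
seed <- 7L
dir.create("results", showWarnings = FALSE)

specs <- sample_structures(35, seed = seed)
labels <- write_label_table(specs |> setNames(vapply(specs, `[[`, "", "protein_id")),
                            "results/structure_labels.csv")
cat(sprintf("sampled %d proteins: alpha 0-%.0f%%, beta 0-%.0f%%, cor(alpha,beta) = %.2f\n",
            nrow(labels), max(labels$frac_alpha_pct), max(labels$frac_beta_pct),
            cor(labels$frac_alpha_pct, labels$frac_beta_pct)))
cat(sprintf("classes: %s\n",
            paste(names(table(labels$class)), table(labels$class),
                  collapse = ", ", sep = " = ")))

# full-scale accounting check (counts only; spectra are not kept)
classes <- labels$class
dup <- labels$protein_id[classes == "alpha_enriched"][1]
single <- labels$protein_id[classes == "beta_enriched"][1]
full_plan <- acquisition_plan(replicate_overrides = setNames(c(2L, 1L), c(dup, single)))
cat(sprintf("full-plan accounting: %d spectra (%d for a triplicate protein)\n",
            plan_spectrum_count(full_plan, specs),
            full_plan$n_cycles * length(full_plan$waiting_times) *
              full_plan$n_detectors * full_plan$n_replicates_default))

# reduced-plan library for the analyses
plan <- acquisition_plan(n_cycles = 1L, waiting_times = c(250, 275, 300),
                         n_detectors = 1L, n_replicates_default = 3L)
lib <- build_library(specs, plan, seed = seed)
cat(sprintf("analysis library: %d spectra of %d proteins\n",
            length(lib$spectra), length(lib$structures)))
write_library(lib, "scratch/library")
cat("library written to scratch/library\n")
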