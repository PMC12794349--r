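test_that("structure sampling respects the library's composition envelope", {
  specs <- sample_structures(35, seed = 7)
  a <- vapply(specs, `[[`, 0, "frac_alpha")
  b <- vapply(specs, `[[`, 0, "frac_beta")
  expect_length(specs, 35)
  expect_true(max(a) <= 0.71)
  expect_true(max(b) <= 0.48)
  expect_true(all(a + b <= 1))
  expect_lt(cor(a, b), 0)
  # parallel-sheet registry: roughly half the set has none
  par <- vapply(specs, `[[`, 0, "frac_parallel")
  expect_gt(mean(par == 0), 0.3)
  expect_true(all(par <= 0.131 + 1e-9))
  # helix lengths cover both regimes
  maxlen <- vapply(specs, function(s)
    if (length(s$helix_lengths)) max(s$helix_lengths) else 0L, 0L)
  expect_true(any(maxlen > 15))
  expect_true(any(maxlen > 0 & maxlen <= 15))
})

test_that("structure sampling is seed-deterministic and validates inputs", {
  expect_identical(sample_structures(35, seed = 7), sample_structures(35, seed = 7))
  specs <- sample_structures(3, seed = 0)
  expect_length(specs, 3)
  for (s in specs) expect_lte(s$frac_alpha + s$frac_beta, 1)
  expect_error(sample_structures(2, seed = 1), "at least 3")
})

test_that("structure_spec enforces its invariants", {
  expect_error(structure_spec("p", 0.5, 0.6, 0.1, 0.5, c(50, 50), 200, 3),
               "exceed 1")
  expect_error(structure_spec("p", 0.25, 0.2, 0.05, 0.1, c(25, 25), 200, 3),
               "frac_parallel")
  expect_error(structure_spec("p", 0.5, 0.1, 0, 0.1, c(10, 10), 200, 3),
               "helix_lengths")
  s <- structure_spec("p", 0.25, 0.2, 0.05, 0.15, c(25, 25), 200, 3)
  expect_s3_class(s, "structure_spec")
  # round trip through the delimited table
  path <- withr::local_tempfile(fileext = ".csv")
  write_structure_table(list(s), path)
  back <- read_structure_table(path)[[1]]
  expect_equal(back[names(back) != "helix_lengths"],
               s[names(s) != "helix_lengths"], tolerance = 1e-12)
  expect_identical(back$helix_lengths, s$helix_lengths)
})

test_that("band model maps structure onto the expected amide I components", {
  pure_alpha <- mk_spec("pa", 0.65, 0, helix_lengths = c(26, 26, 26, 26, 26))
  bands <- bands_from_structure(pure_alpha)
  kinds <- vapply(bands, `[[`, "", "kind")
  expect_true("helix_A" %in% kinds)
  a_band <- bands[[which(kinds == "helix_A")]]
  expect_gt(a_band$center, 1650)   # near 1660, downshifted for 26-residue helices
  expect_lte(a_band$center, 1660)
  expect_false("sheet_perp" %in% kinds)
  expect_true(all(vapply(bands, function(b) b$partner_center < b$center, TRUE)))

  disordered <- mk_spec("coil", 0, 0)
  bands <- bands_from_structure(disordered)
  expect_identical(vapply(bands, `[[`, "", "kind"), "coil")
})

test_that("perpendicular sheet mode shifts down and grows with sheet size", {
  s2 <- mk_spec("s2", 0.1, 0.4, strands = 2)
  s6 <- mk_spec("s6", 0.1, 0.4, strands = 6)
  perp <- function(spec) {
    bands <- bands_from_structure(spec)
    kinds <- vapply(bands, `[[`, "", "kind")
    bands[[which(kinds == "sheet_perp")[1]]]
  }
  expect_lt(perp(s6)$center, perp(s2)$center)
  expect_gt(perp(s6)$amplitude, perp(s2)$amplitude)
})

test_that("rendering places bleach and excited-state absorption correctly", {
  expect_equal(max(abs(render_spectrum(list(), noise_sigma_rel = 0)$amplitude)), 0)

  band <- list(amide2d:::band_component("helix_A", 1660, 1, 10, 7))
  sp <- render_spectrum(band, noise_sigma_rel = 0)
  mn <- arrayInd(which.min(sp$amplitude), dim(sp$amplitude))
  mx <- arrayInd(which.max(sp$amplitude), dim(sp$amplitude))
  expect_equal(sp$pump_axis[mn[1]], 1660, tolerance = 3)
  expect_equal(sp$probe_axis[mn[2]], 1660, tolerance = 1.2)
  expect_equal(sp$probe_axis[mx[2]], 1660 - 16, tolerance = 1.2)

  s1 <- render_spectrum(band, noise_sigma_rel = 0.05, seed = 42)
  s2 <- render_spectrum(band, noise_sigma_rel = 0.05, seed = 42)
  expect_identical(s1$amplitude, s2$amplitude)
})

test_that("beta-rich spectra show the off-diagonal z-pattern coupling", {
  specs <- Filter(function(s) s$frac_beta >= 0.3 && s$frac_antiparallel > 0.2,
                  sample_structures(35, seed = 7))
  expect_gt(length(specs), 2)
  for (spec in specs[1:3]) {
    bands <- bands_from_structure(spec)
    kinds <- vapply(bands, `[[`, "", "kind")
    perp <- bands[[which(kinds == "sheet_perp")[1]]]
    sp <- render_spectrum(bands, noise_sigma_rel = 0)
    at <- function(pump, probe)
      sp$amplitude[which.min(abs(sp$pump_axis - pump)),
                   which.min(abs(sp$probe_axis - probe))]
    cross_mag <- abs(at(1676, perp$center))
    diag_mag <- abs(at(perp$center, perp$center))
    expect_gt(cross_mag, 0.1 * diag_mag)
  }
})

test_that("library accounting follows the acquisition plan", {
  spec <- mk_spec("p1", 0.3, 0.2, strands = 4)
  lib <- build_library(list(spec), acquisition_plan(), seed = 1)
  expect_length(lib$spectra, 198)  # 3 cycles x 11 Tw x 2 detectors x 3 replicates

  lib1 <- build_library(list(spec), unit_plan(), seed = 1)
  expect_length(lib1$spectra, 1)

  # count law for an arbitrary plan with overrides
  specs <- lapply(1:4, function(i) mk_spec(paste0("p", i), 0.2, 0.2))
  plan <- acquisition_plan(n_cycles = 2, waiting_times = c(250, 260),
                           n_detectors = 2, n_replicates_default = 2,
                           replicate_overrides = c(p3 = 1L))
  lib <- build_library(specs, plan, seed = 3)
  expect_length(lib$spectra, plan_spectrum_count(plan, specs))
  expect_length(lib$spectra, (2 + 2 + 1 + 2) * 2 * 2 * 2)
  # groups partition the spectra
  idx <- sort(unname(unlist(lib$groups)))
  expect_identical(idx, seq_along(lib$spectra))
  expect_error(build_library(specs, acquisition_plan(replicate_overrides = c(zz = 2L)),
                             seed = 1), "unknown proteins")
})

test_that("libraries are bit-identical under the same seed", {
  specs <- sample_structures(3, seed = 5)
  l1 <- build_library(specs, reduced_plan(), seed = 9)
  l2 <- build_library(specs, reduced_plan(), seed = 9)
  expect_identical(l1, l2)
  l3 <- build_library(specs, reduced_plan(), seed = 10)
  expect_false(identical(l1$spectra[[1]]$amplitude, l3$spectra[[1]]$amplitude))
})

test_that("library directories round-trip through write/read", {
  specs <- sample_structures(3, seed = 2)
  lib <- build_library(specs, unit_plan(), seed = 2)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir)
  expect_equal(length(back$spectra), length(lib$spectra))
  for (i in seq_along(lib$spectra)) {
    expect_equal(back$spectra[[i]]$amplitude, lib$spectra[[i]]$amplitude,
                 tolerance = 1e-9)
    expect_equal(back$spectra[[i]]$probe_axis, lib$spectra[[i]]$probe_axis,
                 tolerance = 1e-9)
  }
  expect_equal(names(back$groups), names(lib$groups))
  expect_equal(back$structures$protein_01$frac_alpha,
               lib$structures$protein_01$frac_alpha, tolerance = 1e-9)
})
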