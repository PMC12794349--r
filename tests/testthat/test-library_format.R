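test_that("amide region extraction crops inclusively and validates bounds", {
  band <- list(amide2d:::band_component("coil", 1652, 1, 28, 7))
  sp <- render_spectrum(band, noise_sigma_rel = 0)
  same <- extract_amide_region(sp)
  expect_identical(same$amplitude, sp$amplitude)  # identity on the exact grid

  # padded grid with the same interior points crops back to the default case
  pad <- 5
  padded_grid <- list(
    pump = c(seq(1500, 1545, length.out = pad), sp$pump_axis,
             seq(1742, 1800, length.out = pad)),
    probe = c(seq(1500, 1545, length.out = pad), sp$probe_axis,
              seq(1742, 1800, length.out = pad)))
  padded <- render_spectrum(band, grid = padded_grid, noise_sigma_rel = 0)
  cropped <- extract_amide_region(padded)
  expect_identical(dim(cropped$amplitude), c(35L, 85L))
  expect_equal(cropped$amplitude, sp$amplitude)

  expect_error(extract_amide_region(sp, lo = 1737, hi = 1550), "invalid region")
  expect_error(extract_amide_region(sp, lo = 1800, hi = 1900), "intersect")
})

test_that("probe binning aligns axes to the per-pixel mean and is idempotent", {
  specs <- sample_structures(3, seed = 4)
  # zero jitter: axes unchanged
  lib0 <- build_library(specs, unit_plan(calib_jitter = 0), seed = 1)
  expect_identical(bin_probe_axes(lib0)$spectra[[1]]$probe_axis,
                   lib0$spectra[[1]]$probe_axis)

  # two spectra at 1600.5 and 1601.5 average to 1601
  sp1 <- spectrum_2dir(1600, c(1599.5, 1600.5), matrix(0, 1, 2),
                       list(protein_id = "a", replicate = 1, cycle = 1,
                            waiting_time = 250, detector = 1))
  sp2 <- spectrum_2dir(1600, c(1600.5, 1601.5), matrix(0, 1, 2),
                       list(protein_id = "b", replicate = 1, cycle = 1,
                            waiting_time = 250, detector = 1))
  lib <- structure(list(spectra = list(sp1, sp2),
                        structures = list(), groups = list(a = 1L, b = 2L)),
                   class = "spectral_library")
  binned <- bin_probe_axes(lib)
  expect_equal(binned$spectra[[1]]$probe_axis, c(1600, 1601))
  expect_equal(binned$spectra[[2]]$probe_axis, c(1600, 1601))

  # jittered library: one common probe axis afterwards, then a fixed point
  libj <- build_library(specs, reduced_plan(), seed = 6)
  binned <- bin_probe_axes(libj)
  axes <- unique(lapply(binned$spectra, `[[`, "probe_axis"))
  expect_length(axes, 1L)
  expect_identical(bin_probe_axes(binned)$spectra[[1]]$probe_axis,
                   binned$spectra[[1]]$probe_axis)
})

test_that("vectorization is pump-major and invertible", {
  sp <- render_spectrum(list(amide2d:::band_component("coil", 1650, 1, 28, 7)),
                        noise_sigma_rel = 0.02, seed = 3)
  v <- vectorize(sp)
  expect_length(v$row, 2975)
  expect_equal(nrow(v$coords), 2975)

  # single nonzero at (i, j) lands at (i-1)*85 + j
  amp <- matrix(0, 35, 85); amp[7, 19] <- 1
  sp1 <- spectrum_2dir(sp$pump_axis, sp$probe_axis, amp, sp$meta)
  expect_identical(which(vectorize(sp1)$row != 0), (7L - 1L) * 85L + 19L)

  # round trip back to the matrix
  expect_identical(matrix(v$row, 35, 85, byrow = TRUE), sp$amplitude)

  # column count law on an arbitrary grid
  g <- list(pump = seq(1560, 1700, length.out = 12),
            probe = seq(1560, 1700, length.out = 23))
  spg <- render_spectrum(list(), grid = g, noise_sigma_rel = 0)
  expect_length(vectorize(spg)$row, 12 * 23)
})

test_that("diagonal extraction picks the nearest probe pixel per pump point", {
  band <- list(amide2d:::band_component("sheet_perp", 1635, 1, 10, 7))
  sp <- render_spectrum(band, noise_sigma_rel = 0)
  d <- extract_diagonal(sp)
  expect_length(d$row, 35)
  expect_equal(sp$pump_axis[which.min(d$row)], 1635, tolerance = 3)
  # probe coordinate of each diagonal pixel is the closest one available
  expect_true(all(abs(d$coords$probe_cm1 - d$coords$pump_cm1) <=
                    diff(sp$probe_axis)[1] / 2 + 1e-9))
  zero <- spectrum_2dir(sp$pump_axis, sp$probe_axis,
                        matrix(0, 35, 85), sp$meta)
  expect_identical(extract_diagonal(zero)$row, rep(0, 35))
})

test_that("frame assembly is stable, complete and storage-order independent", {
  specs <- sample_structures(3, seed = 8)
  lib <- bin_probe_axes(build_library(specs, reduced_plan(), seed = 8))
  fr <- assemble_frame(lib, "full")
  expect_identical(dim(fr$matrix), c(27L, 2975L))
  frd <- assemble_frame(lib, "diagonal")
  expect_identical(dim(frd$matrix), c(27L, 35L))
  expect_identical(fr$group_of, fr$row_meta$protein_id)

  # permuting the storage order leaves the assembled frame unchanged
  perm <- sample(seq_along(lib$spectra))
  lib_perm <- lib
  lib_perm$spectra <- lib$spectra[perm]
  fr2 <- assemble_frame(lib_perm, "full")
  expect_equal(fr2$matrix, fr$matrix)
  expect_identical(fr2$row_meta, fr$row_meta)

  # single-spectrum library
  lib1 <- build_library(specs[1], unit_plan(), seed = 1)
  expect_identical(nrow(assemble_frame(lib1, "full")$matrix), 1L)

  # duplicate acquisition tuples are an integrity error
  lib_dup <- lib
  lib_dup$spectra[[2]] <- lib_dup$spectra[[1]]
  expect_error(assemble_frame(lib_dup, "full"), "duplicate")
})
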