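test_that("read_xy_spectrum parses, sorts, averages duplicates, and fails loudly", {
  p <- write_lines_tmp(c("# comment", "300 1.0", "200 0.5"))
  raw <- read_xy_spectrum(p)
  expect_equal(raw$abscissa, c(200, 300))
  expect_equal(raw$intensity, c(0.5, 1.0))

  p2 <- write_lines_tmp(c("200,0.4", "200,0.6", "300,1.0"))
  raw2 <- read_xy_spectrum(p2, sep = ",")
  expect_equal(raw2$abscissa, c(200, 300))
  expect_equal(raw2$intensity[1], 0.5)

  p3 <- write_lines_tmp(c("200 0.5", "bad row here"))
  expect_error(read_xy_spectrum(p3), "line 2.*non-numeric")
  p4 <- write_lines_tmp("200 0.5")
  expect_error(read_xy_spectrum(p4), "at least 2")
  expect_error(read_xy_spectrum(tempfile()), "not found")
})

test_that("wavelength-to-energy conversion follows E = hc/lambda", {
  raw <- raw_spectrum(c(200, 354, 500), c(1, 1, 1))
  e <- wavelength_to_energy(raw)
  expect_equal(sort(ev_from_nm(c(200, 354, 500))), e$abscissa)
  expect_equal(ev_from_nm(200), 6.199, tolerance = 1e-4)
  expect_equal(ev_from_nm(354), 3.5024, tolerance = 1e-4)
  expect_true(all(diff(e$abscissa) > 0))
  expect_error(wavelength_to_energy(e), "not in the wavelength domain")
  expect_error(raw_spectrum(c(-1, 200), c(1, 1)) |> wavelength_to_energy(),
               "positive")
})

test_that("Jacobian intensity scaling preserves integrated band area", {
  # flat I(lambda) = c over [lambda1, lambda2]: area must carry over to the
  # energy domain, checked by trapezoid quadrature on a dense grid
  lambda <- seq(300, 600, length.out = 4001)
  cval <- 0.8
  raw <- raw_spectrum(lambda, rep(cval, length(lambda)))
  e <- wavelength_to_energy(raw)
  area_e <- sum(diff(e$abscissa) *
                  (head(e$intensity, -1) + tail(e$intensity, -1)) / 2)
  expect_equal(area_e, cval * (600 - 300), tolerance = 1e-5)
})

test_that("energy/wavelength round trip reproduces the spectrum", {
  raw <- raw_spectrum(seq(250, 700, by = 5),
                      1 + sin(seq(250, 700, by = 5) / 40)^2)
  back <- energy_to_wavelength(wavelength_to_energy(raw))
  expect_equal(back$abscissa, raw$abscissa, tolerance = 1e-9)
  expect_equal(back$intensity, raw$intensity, tolerance = 1e-9)
})

test_that("condition() resamples to a uniform max-normalized grid", {
  expect_equal(cm1_to_ev(100), 0.012398, tolerance = 1e-4)

  e <- seq(1.5, 5.0, by = 0.01)
  y <- 2.7 * exp(-(e - 3)^2 / 0.08)
  raw <- raw_spectrum(e, y, domain = "energy")
  sp <- condition(raw, window = c(2, 4), smoothing = NULL)
  expect_s3_class(sp, "spectrum")
  expect_equal(max(sp$intensities), 1)
  d <- diff(sp$energies)
  expect_lt(max(d) - min(d), 1e-9)
  expect_equal(mean(d), cm1_to_ev(100), tolerance = 1e-9)
  expect_gte(min(sp$energies), 2)
  expect_lte(max(sp$energies), 4)

  # noiseless uniform input with smoothing off reproduces values at nodes
  raw2 <- raw_spectrum(e, y / max(y), domain = "energy")
  sp2 <- condition(raw2, spacing = 0.01, window = c(1.5, 5.0),
                   smoothing = NULL)
  expect_equal(sp2$intensities, y / max(y), tolerance = 1e-9)

  expect_error(condition(raw, window = c(0.5, 4)), "outside data range")
  raw0 <- raw_spectrum(e, rep(0, length(e)) + c(1, rep(0, length(e) - 1)),
                       domain = "energy")
  expect_error(condition(raw0, window = c(3.5, 4.5), smoothing = NULL),
               "degenerate")
})

test_that("condition() is idempotent on its own output", {
  e <- seq(1.5, 5.0, by = 0.005)
  y <- exp(-(e - 2.5)^2 / 0.1) + 0.6 * exp(-(e - 4)^2 / 0.05)
  sp <- condition(raw_spectrum(e, y, domain = "energy"),
                  window = c(2, 4.5), smoothing = NULL)
  sp2 <- condition(raw_spectrum(sp$energies, sp$intensities,
                                domain = "energy"),
                   spacing = grid_spacing(sp), window = sp$window,
                   smoothing = NULL)
  expect_equal(sp2$intensities, sp$intensities, tolerance = 1e-9)
})

test_that("stick spectra read, sort, validate, and flag zero intensity", {
  p <- write_lines_tmp(c("# eV f", "4.1 0.30", "2.2 0.05", "3.0 0.00"))
  st <- read_stick_spectrum(p)
  expect_equal(st$energies, c(2.2, 3.0, 4.1))
  expect_equal(st$strengths, c(0.05, 0.00, 0.30))
  expect_true(has_intensity(st))

  p1 <- write_lines_tmp("3.0 0.0")
  st1 <- read_stick_spectrum(p1)
  expect_false(has_intensity(st1))

  expect_error(stick_spectrum(c(3, -1), c(1, 1)), "positive")
  expect_error(stick_spectrum(c(3, 4), c(1, -0.1)), "non-negative")

  st40 <- gen_sticks(40, c(1.4, 6.2), seed = 11)
  p40 <- tempfile(fileext = ".stk")
  write_stick_spectrum(st40, p40)
  back <- read_stick_spectrum(p40)
  expect_length(back$energies, 40)
  expect_equal(back$energies, st40$energies, tolerance = 1e-7)
})

test_that("XYZ reading detects the metal and validates layout", {
  p <- write_lines_tmp(c("3", "toy", "Fe 0 0 0", "N 2 0 0", "N 0 2 0"),
                       ext = ".xyz")
  s <- read_xyz(p)
  expect_equal(s$metal_index, 1L)
  expect_equal(s$elements, c("Fe", "N", "N"))
  expect_equal(s$coords[2, ], c(2, 0, 0))

  p_bad <- write_lines_tmp(c("5", "bad", "Fe 0 0 0", "N 2 0 0",
                             "N 0 2 0", "N 0 0 2"), ext = ".xyz")
  expect_error(read_xyz(p_bad), "count mismatch")

  p_two <- write_lines_tmp(c("3", "two metals", "Fe 0 0 0", "Fe 3 0 0",
                             "N 0 2 0"), ext = ".xyz")
  expect_error(read_xyz(p_two), "multiple metal candidates")
  expect_equal(read_xyz(p_two, metal_index = 2)$metal_index, 2L)

  # round trip through write_xyz
  toy <- gen_octahedral_toy(2.0, 6)
  pw <- tempfile(fileext = ".xyz")
  write_xyz(toy, pw)
  back <- read_xyz(pw)
  expect_equal(back$coords, toy$coords, tolerance = 1e-7)
  expect_equal(back$elements, toy$elements)
})
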