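test_that("composite Simpson weights integrate polynomials correctly", {
  # odd point count: pure Simpson, exact for cubics
  x <- seq(0, 2, length.out = 21)
  w <- simpson_weights(length(x), x[2] - x[1])
  expect_equal(sum(w * x^3), 4, tolerance = 1e-12)
  # even point count: trapezoid tail, still accurate on dense grids
  x2 <- seq(0, 2, length.out = 20)
  w2 <- simpson_weights(length(x2), x2[2] - x2[1])
  expect_equal(sum(w2 * exp(x2)), exp(2) - 1, tolerance = 1e-3)
  expect_equal(sum(simpson_weights(401, 0.005) *
                     sin(seq(0, 2, by = 0.005))),
               1 - cos(2), tolerance = 1e-10)
})

test_that("similarity is 1 for identical spectra, ~0 for disjoint ones", {
  g <- seq(1, 6, by = 0.005)
  a <- new_spectrum(g, exp(-(g - 3)^2 / 0.1), provenance = "synthetic")
  expect_equal(similarity(a, a), 1, tolerance = 1e-12)

  b <- new_spectrum(g, exp(-(g - 5.5)^2 / 0.002), provenance = "synthetic")
  expect_lt(similarity(a, b), 1e-6)

  g2 <- seq(1, 6, by = 0.004)
  c2 <- new_spectrum(g2, exp(-(g2 - 3)^2 / 0.1), provenance = "synthetic")
  expect_error(similarity(a, c2), "identical energy grid")
})

test_that("similarity matches the Gaussian-overlap closed form", {
  for (sigma in c(0.1, 0.2, 0.35)) {
    for (d in c(0.05, 0.2, 0.5, 0.9)) {
      g <- seq(0, 8, by = 0.002)
      a <- new_spectrum(g, exp(-(g - 3.5)^2 / (2 * sigma^2)),
                        provenance = "synthetic")
      b <- new_spectrum(g, exp(-(g - 3.5 - d)^2 / (2 * sigma^2)),
                        provenance = "synthetic")
      expect_equal(similarity(a, b), gaussian_overlap_similarity(d, sigma),
                   tolerance = 1e-6)
    }
  }
})

test_that("similarity is symmetric and scale-invariant", {
  g <- seq(1.5, 5, by = 0.005)
  set.seed(21)
  ya <- abs(stats::filter(runif(length(g)), rep(1, 25), sides = 2))
  ya[is.na(ya)] <- 0.1
  yb <- exp(-(g - 3)^2 / 0.3)
  a <- new_spectrum(g, as.numeric(ya), provenance = "synthetic")
  b <- new_spectrum(g, yb, provenance = "synthetic")
  expect_equal(similarity(a, b), similarity(b, a), tolerance = 1e-14)
  a_scaled <- new_spectrum(g, as.numeric(ya) * 37.5,
                           provenance = "synthetic")
  expect_equal(similarity(a_scaled, b), similarity(a, b),
               tolerance = 1e-12)
})

test_that("optimizer recovers known shift/broadening without noise", {
  sticks <- gen_sticks(40, c(2.2, 5.8), seed = 42)
  scen <- spectrum_scenario(sticks, delta_true = 0.30, sigma_true = 0.20,
                            noise_level = 0, window = c(2.0, 6.0),
                            seed = 7)
  fit <- optimize_similarity(gen_experimental(scen), sticks)
  expect_equal(fit$delta_opt, 0.30, tolerance = 0.01)
  expect_equal(fit$sigma_opt, 0.20, tolerance = 0.01)
  expect_gte(fit$s_max, 0.999)
  expect_equal(fit$fwhm_opt, fwhm_from_sigma(fit$sigma_opt))
  expect_equal(fit$abs_shift, abs(fit$delta_opt))
  expect_equal(fit$apparent_band_shift, -fit$delta_opt)
})

test_that("single stick against a single Gaussian finds the analytic optimum", {
  g <- seq(1, 5, by = cm1_to_ev(100))
  exp_spec <- new_spectrum(g, exp(-(g - 3)^2 / (2 * 0.25^2)),
                           window = c(1, 5), provenance = "synthetic")
  fit <- optimize_similarity(exp_spec, stick_spectrum(3.0, 0.8))
  expect_equal(fit$delta_opt, 0, tolerance = 0.01)
  expect_equal(fit$sigma_opt, 0.25, tolerance = 0.01)
  expect_gte(fit$s_max, 0.9999)
})

test_that("optimizer is at least as good as an exhaustive grid scan", {
  for (seed in c(3, 14)) {
    sticks <- gen_sticks(20, c(2.4, 4.6), seed = seed)
    scen <- spectrum_scenario(sticks, delta_true = 0.45,
                              sigma_true = 0.18, noise_level = 0.03,
                              window = c(2.2, 4.8), seed = seed + 1)
    exp_spec <- gen_experimental(scen)
    fit <- optimize_similarity(exp_spec, sticks)
    ref <- scan_similarity(exp_spec, sticks, delta_step = 0.05,
                           sigma_step = 0.02)
    expect_gte(fit$s_max, ref$s_max - 1e-4)
  }
})

test_that("enlarging the constraint box never lowers S_max", {
  sticks <- gen_sticks(25, c(2.4, 5.2), seed = 8)
  # truth outside the narrow box so the constraint binds
  scen <- spectrum_scenario(sticks, delta_true = 0.8, sigma_true = 0.3,
                            noise_level = 0, window = c(2.0, 5.6),
                            seed = 9)
  exp_spec <- gen_experimental(scen)
  narrow <- optimize_similarity(exp_spec, sticks,
                                bounds = default_bounds(-0.2, 0.2,
                                                        0.05, 0.15))
  wide <- optimize_similarity(exp_spec, sticks)
  expect_gte(wide$s_max, narrow$s_max - 1e-9)
  expect_true(narrow$delta_opt >= -0.2 - 1e-9 &&
                narrow$delta_opt <= 0.2 + 1e-9)
  expect_true(narrow$sigma_opt >= 0.05 - 1e-9 &&
                narrow$sigma_opt <= 0.15 + 1e-9)
})

test_that("degenerate similarity inputs raise module errors", {
  g <- seq(1, 5, by = 0.01)
  a <- new_spectrum(g, exp(-(g - 3)^2 / 0.1), provenance = "synthetic")
  expect_error(optimize_similarity(a, stick_spectrum(c(2, 3), c(0, 0))),
               "degenerate")
  z <- new_spectrum(g, rep(0, length(g)), provenance = "synthetic",
                    normalize = FALSE)
  expect_error(similarity(a, z), "degenerate")
})
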