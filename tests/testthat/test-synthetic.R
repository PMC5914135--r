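test_that("preset spectra reproduce the calibrated band descriptors", {
  p <- znchl_presets()
  s_m <- synthesize_spectrum(p$monomer)
  s_j1 <- synthesize_spectrum(p$J1)
  s_j2 <- synthesize_spectrum(p$J2)
  mono_win <- c(600, 700); agg_win <- c(690, 800)
  expect_equal(peak_position(s_m, mono_win), 656, tolerance = 1e-5)
  expect_equal(peak_position(s_m, c(400, 460)), 428, tolerance = 1e-5)
  expect_equal(peak_position(s_j1, agg_win), 738, tolerance = 1e-5)
  expect_equal(peak_position(s_j2, agg_win), 749, tolerance = 1e-5)
  expect_equal(band_fwhm(s_m, mono_win), 450, tolerance = 0.01)
  expect_equal(band_fwhm(s_j1, agg_win), 850, tolerance = 0.01)
  expect_equal(band_fwhm(s_j2, agg_win), 510, tolerance = 0.01)
  # calibration property: g at the 745 nm probe hits the targets
  expect_equal(anisotropy_factor(s_j1, 745), -2.7e-3, tolerance = 1e-5 / 2.7e-3)
  expect_equal(anisotropy_factor(s_j2, 745), 9.4e-3, tolerance = 1e-5 / 9.4e-3)
  # couplets are bisignate: one positive, one negative lobe
  for (sp in c("J1", "J2")) {
    signs <- vapply(p[[sp]]$cd_bands, function(b) sign(b$amplitude),
                    numeric(1))
    expect_setequal(signs, c(1, -1))
  }
})

test_that("mixture snapshots reproduce the pure species and the printed band shifts", {
  mono <- generate_mixture_spectrum(c(1, 0, 0))
  j1 <- generate_mixture_spectrum(c(0, 1, 0))
  j2 <- generate_mixture_spectrum(c(0, 0, 1))
  ref <- synthesize_spectrum(znchl_presets()$J1)
  expect_equal(j1$epsilon, ref$epsilon, tolerance = 1e-12)
  expect_equal(j1$delta_epsilon, ref$delta_epsilon, tolerance = 1e-12)
  # monomer -> trapped aggregate: 82 nm; monomer -> fiber: 93 nm
  expect_equal(band_shift(mono, j1, c(600, 800)), 82, tolerance = 1e-3)
  expect_equal(band_shift(mono, j2, c(600, 800)), 93, tolerance = 1e-3)
  expect_equal(band_shift(j1, j2, c(690, 800)), 11, tolerance = 1e-3)
  expect_error(generate_mixture_spectrum(c(0.6, 0.6, -0.2)), "fractions")
  expect_error(generate_mixture_spectrum(c(0.5, 0.4, 0.2)), "sum")
})

test_that("band_shift windows spanning both bands use the dominant maximum", {
  # the 600-800 nm window contains the monomer Qy and the aggregate band;
  # a mixture dominated by one species must locate that species' peak
  j2_heavy <- generate_mixture_spectrum(c(0.05, 0, 0.95))
  expect_equal(peak_position(j2_heavy, c(690, 800)), 749, tolerance = 0.01)
})

test_that("concentration-series generator is a noiseless passthrough and seed-reproducible", {
  co <- preset_coefficients()
  p <- znchl_presets()$thermo
  grid <- default_concentration_grid()
  expect_equal(grid[1], 5e-7)
  expect_equal(grid[length(grid)], 3e-5)
  clean <- generate_concentration_series(p, co, grid, no_noise())
  expect_equal(clean, observable_series(p, co, grid), tolerance = 1e-15)
  n1 <- generate_concentration_series(p, co, grid, noise_spec(seed = 5))
  n2 <- generate_concentration_series(p, co, grid, noise_spec(seed = 5))
  n3 <- generate_concentration_series(p, co, grid, noise_spec(seed = 6))
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("kinetic trace generator matches its presets and is seed-reproducible", {
  t <- seq(0, 24, by = 0.02)
  still <- generate_kinetic_trace("1:99", t)
  expect_equal(still$g, rep(-2.7e-3, length(t)))
  fast <- generate_kinetic_trace("30:70", t)
  expect_equal(initial_rate(fast)$rate, 8.6e-3, tolerance = 0.03)
  expect_error(generate_kinetic_trace("50:50", t), "30:70")
  ns <- noise_spec(add_g = 1e-4, seed = 21)
  a <- generate_kinetic_trace("20:80", t, ns)
  b <- generate_kinetic_trace("20:80", t, ns)
  expect_identical(a$g, b$g)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_concentration_series(noise = noise_spec(seed = 1)))
  invisible(generate_kinetic_trace("30:70", 0:10,
                                   noise_spec(add_g = 1e-4, seed = 2)))
  expect_identical(.Random.seed, before)
})

test_that("series CSV round-trips with probe wavelength metadata", {
  ser <- generate_concentration_series(noise = noise_spec(seed = 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ser, f)
  r <- read_series_csv(f)
  expect_identical(r$c_total_M, ser$c_total_M)
  expect_identical(r$epsilon_obs, ser$epsilon_obs)
  expect_identical(r$delta_epsilon_obs, ser$delta_epsilon_obs)
  expect_equal(attr(r, "lambda_A_nm"), 750)
  expect_equal(attr(r, "lambda_C_nm"), 746)
})
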