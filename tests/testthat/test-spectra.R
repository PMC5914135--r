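test_that("nm/wavenumber conversion is exact and involutive", {
  expect_equal(nm_to_wavenumber(1000), 10000)
  expect_equal(nm_to_wavenumber(656), 1e7 / 656, tolerance = 1e-12)
  x <- c(0.3, 1, 428, 656, 749, 1e4)
  expect_equal(nm_to_wavenumber(nm_to_wavenumber(x)), x, tolerance = 1e-12)
  expect_error(nm_to_wavenumber(0), "positive")
  expect_error(nm_to_wavenumber(-5), "positive")
})

test_that("spectrum construction enforces its invariants", {
  expect_error(dye_spectrum(c(500, 400), c(1, 1)), "increasing")
  expect_error(dye_spectrum(c(400, 400), c(1, 1)), "increasing")
  expect_error(dye_spectrum(c(-1, 400), c(1, 1)), "positive")
  expect_error(dye_spectrum(c(400, 500), c(-1, 1)), "non-negative")
  expect_error(dye_spectrum(c(400, 500), c(1, NA)), "finite")
  expect_error(dye_spectrum(c(400, 500), c(1, 1), c(1, 2, 3)), "lengths")
  s <- dye_spectrum(c(400, 500), c(1, 2), c(-0.1, 0.2))
  expect_true(has_cd_channel(s))
  expect_false(has_cd_channel(dye_spectrum(c(400, 500), c(1, 2))))
})

test_that("synthesized Gaussian bands attain amplitude at center and half of it at FWHM/2", {
  ctr <- 700; fw <- 600
  # grid containing the center and the exact half-max wavenumbers
  nu0 <- nm_to_wavenumber(ctr)
  grid <- sort(nm_to_wavenumber(c(nu0 + fw / 2, nu0, nu0 - fw / 2)))
  s <- synthesize_spectrum(
    species_model("monomer", gaussian_band(ctr, 2.5, fw)), grid)
  expect_equal(s$epsilon[2], 2.5, tolerance = 1e-12)
  expect_equal(s$epsilon[c(1, 3)], rep(1.25, 2), tolerance = 1e-12)
  expect_error(synthesize_spectrum(
    species_model("monomer", gaussian_band(ctr, 2.5, fw)), numeric(0)),
    "empty")
})

test_that("anisotropy factor is delta_epsilon/epsilon with linear interpolation", {
  g <- seq(600, 700, 1)
  s0 <- dye_spectrum(g, rep(2, length(g)), rep(0, length(g)))
  expect_equal(anisotropy_factor(s0, 650), 0)
  r <- -3.7e-3
  eps <- 1 + (g - 600) / 50
  s1 <- dye_spectrum(g, eps, r * eps)
  for (w in c(600, 633.25, 699.9))
    expect_equal(anisotropy_factor(s1, w), r, tolerance = 1e-12)
  # invariance under common positive rescaling of both channels
  s2 <- dye_spectrum(g, 7.3 * eps, 7.3 * r * eps)
  expect_equal(anisotropy_factor(s2, 654.5), anisotropy_factor(s1, 654.5),
               tolerance = 1e-12)
  expect_error(anisotropy_factor(dye_spectrum(g, eps), 650), "CD channel")
  sz <- dye_spectrum(g, c(0, eps[-1]), r * eps)
  expect_error(anisotropy_factor(sz, 600), "zero")
  expect_error(anisotropy_factor(s1, 710), "outside")
})

test_that("band_fwhm recovers the generating width and matches the Gaussian sigma relation", {
  for (fw in c(450, 510, 850)) {
    s <- single_band_spectrum(fwhm_cm = fw)
    expect_equal(band_fwhm(s, c(690, 800)), fw, tolerance = 0.01)
  }
  # FWHM = 2 sqrt(2 ln 2) sigma: synthesize from sigma, recover FWHM
  sigma <- 300
  fw <- 2 * sqrt(2 * log(2)) * sigma
  s <- single_band_spectrum(center_nm = 700, fwhm_cm = fw,
                            grid = seq(600, 820, 0.5))
  expect_equal(band_fwhm(s, c(640, 780)), fw, tolerance = 0.01)
})

test_that("band_fwhm errors name the truncated side", {
  s <- single_band_spectrum(center_nm = 749, fwhm_cm = 850)
  expect_error(band_fwhm(s, c(735, 800)), "blue")
  expect_error(band_fwhm(s, c(690, 755)), "red")
})

test_that("peak_position refines to sub-gridpoint accuracy and rejects monotone windows", {
  s <- single_band_spectrum(center_nm = 713.3, fwhm_cm = 510,
                            grid = seq(650, 780, 0.5))
  expect_equal(peak_position(s, c(690, 740)), 713.3, tolerance = 0.01)
  expect_error(peak_position(s, c(740, 780)), "monotone|maximum")
})

test_that("band_shift is antisymmetric and zero for identical spectra", {
  a <- single_band_spectrum(center_nm = 700)
  b <- single_band_spectrum(center_nm = 711)
  win <- c(650, 780)
  expect_equal(band_shift(a, a, win), 0, tolerance = 1e-9)
  expect_equal(band_shift(a, b, win), 11, tolerance = 0.01)
  expect_equal(band_shift(a, b, win), -band_shift(b, a, win),
               tolerance = 1e-9)
})

test_that("spectrum CSV round-trips at full precision and validates on read", {
  s <- synthesize_spectrum(znchl_presets()$J2, seq(690, 800, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, f)
  r <- read_spectrum_csv(f)
  expect_identical(r$wavelength_nm, s$wavelength_nm)
  expect_identical(r$epsilon, s$epsilon)
  expect_identical(r$delta_epsilon, s$delta_epsilon)

  # optional CD channel absent
  s2 <- dye_spectrum(c(400, 401, 402), c(1, 2, 1))
  write_spectrum_csv(s2, f)
  expect_false(has_cd_channel(read_spectrum_csv(f)))

  # decreasing grid rejected with the offending row named
  writeLines(c("wavelength_nm,epsilon", "500,1", "400,2"), f)
  expect_error(read_spectrum_csv(f), "row 2")
  writeLines(c("wavelength_nm,foo", "500,1"), f)
  expect_error(read_spectrum_csv(f), "missing column")
})
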