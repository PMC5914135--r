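test_that("thermo_params validates and exposes cooperativity", {
  p <- paper_constants()
  expect_equal(cooperativity(p), 2.4e-2 / 1.0e5)
  expect_error(thermo_params(0, 1, 1), "positive")
  expect_error(thermo_params(1, 1, 1, T_K = -5), "positive")
})

test_that("free monomer approaches c_T when aggregation vanishes", {
  p <- thermo_params(K_J1 = 1e-12, K_N = 1e-12, K_J2 = 1e-12)
  for (cT in c(1e-7, 1e-5, 1e-3))
    expect_equal(free_monomer(p, cT), cT, tolerance = 1e-6)
})

test_that("isodesmic limit matches the closed-form quadratic", {
  # K_N = K_J2 = K, K_J1 ~ 0: c_T = m/(1 - K m)^2, so at K c_T = 1 the
  # scaled root is x = (3 - sqrt(5))/2
  p <- thermo_params(K_J1 = 1e-16, K_N = 1e5, K_J2 = 1e5)
  m <- free_monomer(p, 1e-5)
  x_expect <- (3 - sqrt(5)) / 2
  expect_equal(p$K_J2 * m, x_expect, tolerance = 1e-9)
  expect_equal(m, 3.8197e-6, tolerance = 1e-4)
  # algebraic identity over a range of concentrations
  for (cT in 10^seq(-7, -4, by = 0.5)) {
    m <- free_monomer(p, cT)
    expect_equal(m / (1 - p$K_J2 * m)^2, cT, tolerance = 1e-9)
  }
})

test_that("reference constants give the expected free monomer and trace polymer at 1e-5 M", {
  p <- paper_constants()
  m <- free_monomer(p, 1e-5)
  expect_equal(m, 8.236e-6, tolerance = 1e-3)
  d <- species_distribution(p, 1e-5)
  expect_lt(d$phi_polymer, 1e-4)
  # cross-check against the truncated-series oracle
  expect_equal(truncated_sum_oracle(p, m, 500)$total, 1e-5,
               tolerance = 1e-10)
})

test_that("closed-form mass balance agrees with the truncated-sum oracle over random parameters", {
  set.seed(42)
  for (i in 1:40) {
    p <- thermo_params(K_J1 = 10^runif(1, 0, 6),
                       K_N = 10^runif(1, -4, 4),
                       K_J2 = 10^runif(1, 2, 7))
    x <- runif(1, 0.01, 0.99)
    m <- x / p$K_J2
    o <- truncated_sum_oracle(p, m, 12000L)
    closed <- m + 2 * p$K_J1 * m^2 +
      p$K_N * m^2 * (2 - x) / (1 - x)^2
    expect_lt(o$last_term, 1e-15 * closed)
    expect_equal(o$total, closed, tolerance = 1e-10)
  }
})

test_that("truncated sum handles its edge cases", {
  p <- thermo_params(1e3, 1e2, 1e5)
  m <- 1e-6
  expect_equal(truncated_sum_oracle(p, m, 2)$total,
               m + 2 * p$K_J1 * m^2 + 2 * p$K_N * m^2, tolerance = 1e-14)
  expect_error(truncated_sum_oracle(p, 2e-5, 100), "diverges")
  # vanishing elongation: only monomer + dimers remain
  p0 <- thermo_params(1e3, 1e2, 1e-12)
  expect_equal(truncated_sum_oracle(p0, m, 400)$total,
               m + 2 * p0$K_J1 * m^2 + 2 * p0$K_N * m^2, tolerance = 1e-9)
})

test_that("species distribution conserves mass and obeys the dilution limit", {
  p <- paper_constants()
  cT <- 10^seq(-12, log10(3e-5), length.out = 25)
  d <- species_distribution(p, cT)
  expect_true(all(abs(d$phi_mono + d$phi_dimer + d$phi_polymer - 1) < 1e-9))
  expect_true(all(d$m > 0 & d$m <= d$c_T))
  expect_true(all(p$K_J2 * d$m < 1))
  expect_gt(d$phi_mono[1], 0.999)
  expect_true(all(d$dp_n >= 2 | d$phi_polymer == 0))
  # monotonicity in c_T
  expect_true(all(diff(d$m) > 0))
  expect_true(all(diff(d$phi_polymer) > -1e-12))
  # polymer overtakes dimer by 3e-5 M
  d3 <- species_distribution(p, 3e-5)
  expect_gt(d3$phi_polymer, d3$phi_dimer)
})

test_that("cooperative systems switch on sharply around the elongation concentration", {
  p <- thermo_params(K_J1 = 1e-12, K_N = 1e-1, K_J2 = 1e5)  # sigma = 1e-6
  ce <- elongation_concentration(p)
  expect_equal(ce, 1e-5)
  lo <- species_distribution(p, ce / sqrt(10))$phi_polymer
  hi <- species_distribution(p, ce * sqrt(10))$phi_polymer
  expect_lt(lo, 0.01)
  expect_gt(hi, 0.5)
  # reciprocal scaling
  p2 <- thermo_params(p$K_J1, p$K_N, 2 * p$K_J2)
  expect_equal(elongation_concentration(p2), ce / 2)
  # reference constants: onset concentration sits below the observed
  # intensification threshold of 1.2e-5 M
  expect_lt(elongation_concentration(paper_constants()), 1.2e-5)
})

test_that("observable series is a convex combination of the species coefficients", {
  p <- paper_constants()
  cT <- default_concentration_grid()
  co_equal <- observable_coefficients(
    eps = c(monomer = 2, J1 = 2, J2 = 2),
    deps = c(monomer = -1, J1 = -1, J2 = -1),
    lambda_A_nm = 750, lambda_C_nm = 746)
  s <- observable_series(p, co_equal, cT)
  expect_equal(s$epsilon_obs, rep(2, length(cT)), tolerance = 1e-9)
  expect_equal(s$delta_epsilon_obs, rep(-1, length(cT)), tolerance = 1e-9)

  co <- observable_coefficients(
    eps = c(monomer = 1, J1 = 0.4, J2 = 1.7),
    deps = c(monomer = 0, J1 = -0.2, J2 = 0.9),
    lambda_A_nm = 750, lambda_C_nm = 746)
  s2 <- observable_series(p, co, cT)
  expect_true(all(s2$epsilon_obs >= min(co$eps) - 1e-12 &
                    s2$epsilon_obs <= max(co$eps) + 1e-12))
  expect_true(all(s2$delta_epsilon_obs >= min(co$deps) - 1e-12 &
                    s2$delta_epsilon_obs <= max(co$deps) + 1e-12))
})

test_that("dilute observables stay within 2% of the monomer coefficient at a monomer probe", {
  p <- paper_constants()
  # probe the monomer Qy band, where the aggregates barely absorb
  co <- preset_coefficients(lambda_A_nm = 656, lambda_C_nm = 746)
  s <- observable_series(p, co, 5e-7)
  expect_equal(s$epsilon_obs, unname(co$eps["monomer"]), tolerance = 0.02)
})
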