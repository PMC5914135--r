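#' Noise specification for the generators
#'
#' Seeded Gaussian noise applied by the synthetic-data generators:
#' multiplicative (relative sd) and additive (absolute sd) per channel.
#' True experimental noise levels are not published for this system; the
#' defaults (1% on epsilon, 2% on delta-epsilon) are conventional
#' spectroscopy-grade values.
#'
#' @param mult_epsilon,mult_delta_epsilon Relative sd of multiplicative
#'   noise on the absorption / CD channel.
#' @param add_epsilon,add_delta_epsilon Absolute sd of additive noise per
#'   channel (same units as the channel).
#' @param add_g Absolute sd of additive noise on kinetic g(t) samples.
#' @param seed Integer seed; every generator is bit-reproducible under a
#'   fixed seed.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(mult_epsilon = 0.01, mult_delta_epsilon = 0.02,
                       add_epsilon = 0, add_delta_epsilon = 0,
                       add_g = 0, seed = 1729L) {
  vals <- c(mult_epsilon, mult_delta_epsilon, add_epsilon,
            add_delta_epsilon, add_g)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise standard deviations must be finite and >= 0", call. = FALSE)
  structure(list(mult_epsilon = mult_epsilon,
                 mult_delta_epsilon = mult_delta_epsilon,
                 add_epsilon = add_epsilon,
                 add_delta_epsilon = add_delta_epsilon,
                 add_g = add_g, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
no_noise <- function(seed = 1729L) {
  noise_spec(0, 0, 0, 0, 0, seed = seed)
}

# evaluate expr with a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.preset_cache <- new.env(parent = emptyenv())

# species absorption / CD value at one wavelength, straight from the bands
.model_eps <- function(model, nm) .eval_bands(model$absorption_bands, nm)
.model_deps <- function(model, nm) {
  if (!length(model$cd_bands)) return(0)
  .eval_bands(model$cd_bands, nm)
}

# scale a unit couplet so that g at the probe wavelength hits its target
.calibrate_couplet <- function(absorption_bands, lobe_pos, lobe_neg,
                               fwhm_cm, probe_nm, g_target) {
  eps <- .eval_bands(absorption_bands, probe_nm)
  unit <- list(gaussian_band(lobe_pos, 1, fwhm_cm),
               gaussian_band(lobe_neg, -1, fwhm_cm))
  d_unit <- .eval_bands(unit, probe_nm)
  if (abs(d_unit) < 1e-12 || sign(d_unit) != sign(g_target))
    stop(sprintf(
      "cannot calibrate couplet (+%g/-%g nm) to g(%g nm) = %g: unit couplet value %g",
      lobe_pos, lobe_neg, probe_nm, g_target, d_unit), call. = FALSE)
  a <- g_target * eps / d_unit
  list(gaussian_band(lobe_pos, a, fwhm_cm),
       gaussian_band(lobe_neg, -a, fwhm_cm))
}

#' Calibrated spectral, thermodynamic and kinetic presets
#'
#' The three species models and the reference parameter set the generators
#' are built on, calibrated to the published signatures of the zinc chlorin
#' system:
#' * monomer: Soret band at 428 nm plus Qy band at 656 nm (FWHM
#'   450 cm^-1), CD-silent;
#' * J1 (trapped nanoparticle dimers): broad Qy at 738 nm (FWHM 850 cm^-1)
#'   with a weak bisignate couplet (+725/-749 nm) scaled so
#'   g(745 nm) = -2.7e-3;
#' * J2 (equilibrated helical fibers): narrow, intensified Qy at 749 nm
#'   (FWHM 510 cm^-1) with a strong couplet (+745/-760 nm) scaled so
#'   g(745 nm) = +9.4e-3;
#' * equilibrium constants K_J1 = 1.3e4, K_N = 2.4e-2, K_J2 = 1.0e5 M^-1
#'   at 293 K;
#' * initial transformation rates by MeOH:water ratio: 30:70 -> 8.6e-3,
#'   20:80 -> 2.5e-3, 10:90 -> 0.4e-3, 1:99 -> 0 h^-1, all between
#'   g_start = -2.7e-3 and g_end = +9.4e-3.
#'
#' Absolute absorptivities are in normalized units (monomer Qy peak = 1);
#' every descriptor the package reports (g, FWHM, peak positions,
#' equilibrium constants, rates) is invariant to that overall scale. The
#' couplet amplitudes are calibrated numerically at construction and the
#' result is cached; construction fails if a g target cannot be reached
#' with the stated lobe positions.
#'
#' @return A `znchl_presets` list with elements `monomer`, `J1`, `J2`
#'   ([species_model()]s), `thermo` ([thermo_params()]), `kinetics`
#'   (data frame of conditions), `g_targets` and `probe_nm`.
#' @export
znchl_presets <- function() {
  if (!is.null(.preset_cache$presets)) return(.preset_cache$presets)
  probe_nm <- 745
  g_targets <- c(J1 = -2.7e-3, J2 = 9.4e-3)

  mono_bands <- list(gaussian_band(428, 1.8, 1200),
                     gaussian_band(656, 1.0, 450))
  j1_abs <- list(gaussian_band(738, 0.7, 850))
  j2_abs <- list(gaussian_band(749, 1.5, 510))

  j1_cd <- .calibrate_couplet(j1_abs, 725, 749, 850, probe_nm,
                              g_targets[["J1"]])
  j2_cd <- .calibrate_couplet(j2_abs, 745, 760, 510, probe_nm,
                              g_targets[["J2"]])

  presets <- structure(list(
    monomer = species_model("monomer", mono_bands),
    J1 = species_model("J1", j1_abs, j1_cd),
    J2 = species_model("J2", j2_abs, j2_cd),
    thermo = thermo_params(K_J1 = 1.3e4, K_N = 2.4e-2, K_J2 = 1.0e5,
                           T_K = 293),
    kinetics = data.frame(
      condition = c("30:70", "20:80", "10:90", "1:99"),
      water_pct = c(70, 80, 90, 99),
      rate_per_h = c(8.6e-3, 2.5e-3, 0.4e-3, 0),
      g_start = -2.7e-3, g_end = 9.4e-3,
      stringsAsFactors = FALSE),
    g_targets = g_targets,
    probe_nm = probe_nm,
    version = "1"), class = "znchl_presets")

  # calibration check: synthesized aggregate spectra must hit the g targets
  for (sp in c("J1", "J2")) {
    g <- anisotropy_factor(synthesize_spectrum(presets[[sp]]), probe_nm)
    if (abs(g - g_targets[[sp]]) > 1e-5)
      stop(sprintf("preset calibration failed for %s: g(%g) = %g, target %g",
                   sp, probe_nm, g, g_targets[[sp]]), call. = FALSE)
  }
  .preset_cache$presets <- presets
  presets
}

#' Observable coefficients implied by the presets
#'
#' Per-species epsilon at the absorption probe wavelength and delta-epsilon
#' at the CD probe wavelength, evaluated directly from the preset band
#' models (defaults: 750 nm and 746 nm, the probe wavelengths of the
#' concentration-series analysis).
#'
#' @param presets A [znchl_presets()] list.
#' @param lambda_A_nm,lambda_C_nm Probe wavelengths in nm.
#' @return An [observable_coefficients()].
#' @export
preset_coefficients <- function(presets = znchl_presets(),
                                lambda_A_nm = 750, lambda_C_nm = 746) {
  sp <- c("monomer", "J1", "J2")
  observable_coefficients(
    eps = stats::setNames(
      vapply(sp, function(s) .model_eps(presets[[s]], lambda_A_nm),
             numeric(1)), sp),
    deps = stats::setNames(
      vapply(sp, function(s) .model_deps(presets[[s]], lambda_C_nm),
             numeric(1)), sp),
    lambda_A_nm = lambda_A_nm, lambda_C_nm = lambda_C_nm)
}

#' Default concentration grid of the dilution study
#'
#' 15 log-spaced total concentrations from 5e-7 to 3e-5 M, the range over
#' which the system moves from dominantly monomeric through the dimer
#' regime into cooperative fiber growth.
#'
#' @param n Number of grid points.
#' @param c_min,c_max Grid endpoints in M.
#' @return Numeric vector of concentrations, M.
#' @export
default_concentration_grid <- function(n = 15L, c_min = 5e-7,
                                       c_max = 3e-5) {
  10^seq(log10(c_min), log10(c_max), length.out = n)
}

#' Generate a synthetic concentration series
#'
#' Equilibrium observables on a concentration grid (via
#' [observable_series()]) perturbed by seeded noise. With zero noise the
#' output equals [observable_series()] exactly.
#'
#' @param params A [thermo_params()]; defaults to the preset constants.
#' @param coeffs An [observable_coefficients()]; defaults to the preset
#'   coefficients at 750/746 nm.
#' @param grid Total concentrations, M.
#' @param noise A [noise_spec()].
#' @return Data frame as from [observable_series()].
#' @export
generate_concentration_series <- function(params = znchl_presets()$thermo,
                                          coeffs = preset_coefficients(),
                                          grid = default_concentration_grid(),
                                          noise = no_noise()) {
  stopifnot(inherits(noise, "noise_spec"))
  out <- observable_series(params, coeffs, grid)
  n <- nrow(out)
  .with_seed(noise$seed, {
    out$epsilon_obs <- out$epsilon_obs *
      (1 + noise$mult_epsilon * stats::rnorm(n)) +
      noise$add_epsilon * stats::rnorm(n)
    out$delta_epsilon_obs <- out$delta_epsilon_obs *
      (1 + noise$mult_delta_epsilon * stats::rnorm(n)) +
      noise$add_delta_epsilon * stats::rnorm(n)
  })
  out
}

#' Generate a synthetic kinetic trace for a preset condition
#'
#' Single-exponential g(t) trace ([simulate_trace()]) with the preset
#' endpoints and initial rate of the requested MeOH:water condition, plus
#' seeded additive noise on g.
#'
#' @param condition One of the preset condition labels
#'   (`"30:70"`, `"20:80"`, `"10:90"`, `"1:99"`).
#' @param time_h Sampling times, hours.
#' @param noise A [noise_spec()] (`add_g` is the relevant channel).
#' @param presets A [znchl_presets()] list.
#' @return A [kinetic_trace()].
#' @export
generate_kinetic_trace <- function(condition,
                                   time_h = seq(0, 24, by = 0.02),
                                   noise = no_noise(),
                                   presets = znchl_presets()) {
  stopifnot(inherits(noise, "noise_spec"))
  k <- presets$kinetics
  i <- match(condition, k$condition)
  if (is.na(i))
    stop(sprintf("unknown condition '%s'; valid conditions: %s",
                 condition, paste(k$condition, collapse = ", ")),
         call. = FALSE)
  tr <- simulate_trace(k$g_start[i], k$g_end[i], k$rate_per_h[i], time_h,
                       condition = condition, c_T = 1e-5, T_K = 293)
  if (noise$add_g > 0) {
    .with_seed(noise$seed + i, {
      tr$g <- tr$g + noise$add_g * stats::rnorm(length(tr$g))
    })
  }
  tr
}

#' Generate a mixture snapshot spectrum
#'
#' Population-weighted sum of the three preset species spectra — a snapshot
#' of the system at given mass fractions — with seeded multiplicative
#' noise per channel.
#'
#' @param fractions Numeric length 3, `(phi_mono, phi_dimer, phi_polymer)`;
#'   each in `[0, 1]`, summing to 1 within 1e-9.
#' @param grid_nm Wavelength grid, nm.
#' @param noise A [noise_spec()].
#' @param presets A [znchl_presets()] list.
#' @return A [dye_spectrum()] with both channels.
#' @export
generate_mixture_spectrum <- function(fractions, grid_nm = default_grid(),
                                      noise = no_noise(),
                                      presets = znchl_presets()) {
  stopifnot(inherits(noise, "noise_spec"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be (phi_mono, phi_dimer, phi_polymer) in [0,1] summing to 1",
         call. = FALSE)
  specs <- lapply(c("monomer", "J1", "J2"),
                  function(s) synthesize_spectrum(presets[[s]], grid_nm))
  eps <- Reduce(`+`, Map(function(s, f) f * s$epsilon, specs,
                         as.list(fractions)))
  de <- Reduce(`+`, Map(function(s, f) {
    if (is.null(s$delta_epsilon)) 0 * grid_nm else f * s$delta_epsilon
  }, specs, as.list(fractions)))
  n <- length(grid_nm)
  .with_seed(noise$seed, {
    eps <- pmax(0, eps * (1 + noise$mult_epsilon * stats::rnorm(n)) +
                  noise$add_epsilon * stats::rnorm(n))
    de <- de * (1 + noise$mult_delta_epsilon * stats::rnorm(n)) +
      noise$add_delta_epsilon * stats::rnorm(n)
  })
  dye_spectrum(grid_nm, eps, de)
}
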