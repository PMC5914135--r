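#' Standard Gibbs energy of an equilibrium
#'
#' \eqn{\Delta G^\circ = -RT \ln K} with R = 8.31446 J mol^-1 K^-1,
#' returned in kJ mol^-1. A binding constant above 1 M^-1 gives a negative
#' (favourable) Gibbs energy; K < 1 M^-1 a positive one.
#'
#' @param K Equilibrium constant(s), M^-1 (> 0). Vectorized.
#' @param T_K Absolute temperature, K (> 0).
#' @return Gibbs energy in kJ mol^-1.
#' @export
gibbs_energy <- function(K, T_K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("K must be positive and finite", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0)
    stop("T_K must be positive", call. = FALSE)
  -8.31446 * T_K * log(K) / 1000
}

#' Gibbs energy landscape of the competing pathways
#'
#' Converts the three equilibrium constants to standard Gibbs energies at
#' the parameter set's temperature. The nucleation step is flagged as
#' rate-limiting when its Gibbs energy is the landscape maximum — for a
#' cooperative system (sigma << 1) nucleation is the energetically most
#' unfavourable step separating the trapped dimer state from the
#' equilibrated fibers.
#'
#' @param params A [thermo_params()].
#' @return Data frame of class `energy_landscape` with columns `process`,
#'   `K`, `dG_kJ_per_mol`, `T_K`, `rate_limiting`.
#' @export
energy_landscape <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  K <- c(params$K_J1, params$K_N, params$K_J2)
  dG <- gibbs_energy(K, params$T_K)
  out <- data.frame(
    process = c("off-pathway dimerization", "nucleation", "elongation"),
    K = K,
    dG_kJ_per_mol = dG,
    T_K = params$T_K,
    rate_limiting = dG == max(dG))
  class(out) <- c("energy_landscape", "data.frame")
  out
}

#' Options for the concentration-series fit
#'
#' @param n_starts Number of jittered initializations (best objective wins,
#'   ties broken by smallest K_N).
#' @param start_jitter_decades Uniform jitter half-width applied to the
#'   log10 of each initial constant.
#' @param seed Seed controlling start jitter (and the bootstrap, if any).
#' @param lower_log10,upper_log10 Box bounds on log10 of
#'   (K_J1, K_N, K_J2).
#' @param maxiter Levenberg-Marquardt iteration budget per start.
#' @param pin_monomer Optional numeric `c(eps, deps)` pinning the monomer
#'   coefficients (e.g. from dilute-regime spectra) instead of co-fitting.
#' @param weighting `"magnitude"` (default) weights each residual by the
#'   inverse observed magnitude (floored at 5% of the channel range) —
#'   the inverse-standard-deviation weighting implied by multiplicative
#'   spectroscopic noise, which keeps the information-rich dilute regime
#'   from being swamped by the intense high-concentration points.
#'   `"range"` uses uniform per-channel weights (each channel normalized
#'   by its observed range only).
#' @param n_boot Residual-bootstrap resamples for parameter uncertainty
#'   (0 = none).
#' @return List of options for [fit_concentration_series()].
#' @export
fit_options <- function(n_starts = 5L, start_jitter_decades = 1,
                        seed = 1729L,
                        lower_log10 = c(-8, -8, -8),
                        upper_log10 = c(12, 12, 12),
                        maxiter = 400L,
                        pin_monomer = NULL,
                        weighting = c("magnitude", "range"),
                        n_boot = 0L) {
  list(n_starts = as.integer(n_starts),
       start_jitter_decades = start_jitter_decades,
       seed = as.integer(seed),
       lower_log10 = lower_log10, upper_log10 = upper_log10,
       maxiter = as.integer(maxiter),
       pin_monomer = pin_monomer,
       weighting = match.arg(weighting),
       n_boot = as.integer(n_boot))
}

# per-point weights for one channel; both schemes also normalize by the
# channel range so the two channels contribute comparably
.channel_weights <- function(y, weighting) {
  rng <- diff(range(y))
  if (weighting == "magnitude") 1 / (abs(y) + 0.05 * rng)
  else rep(1 / rng, length(y))
}

# Variable projection: given the three constants, the six observable
# coefficients enter linearly and are solved per channel by weighted least
# squares. Epsilon coefficients are kept non-negative by an active set.
.solve_coeffs <- function(phi, y, w, nonneg, pin = NULL) {
  if (!is.null(pin)) {
    y <- y - phi[, 1] * pin
    phi <- phi[, 2:3, drop = FALSE]
  }
  wls <- function(cols) tryCatch(qr.solve(phi[, cols, drop = FALSE] * w,
                                          y * w),
                                 error = function(e) rep(0, sum(cols)))
  a <- wls(rep(TRUE, ncol(phi)))
  flagged <- FALSE
  if (nonneg) {
    active <- rep(TRUE, length(a))
    for (pass in seq_len(length(a))) {
      if (all(a[active] >= 0)) break
      flagged <- TRUE
      active[active][which.min(a[active])] <- FALSE
      a[] <- 0
      if (any(active)) a[active] <- wls(active)
    }
    a[a < 0] <- 0
  }
  if (!is.null(pin)) a <- c(pin, a)
  list(coef = a, flagged = flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.varpro_eval <- function(log10K, series, weights, T_K, pin_monomer) {
  params <- thermo_params(10^log10K[1], 10^log10K[2], 10^log10K[3], T_K)
  d <- species_distribution(params, series$c_total_M)
  phi <- as.matrix(d[, c("phi_mono", "phi_dimer", "phi_polymer")])
  se <- .solve_coeffs(phi, series$epsilon_obs, weights$epsilon,
                      nonneg = TRUE,
                      pin = if (!is.null(pin_monomer)) pin_monomer[1])
  sc <- .solve_coeffs(phi, series$delta_epsilon_obs, weights$delta_epsilon,
                      nonneg = FALSE,
                      pin = if (!is.null(pin_monomer)) pin_monomer[2])
  fit_e <- as.numeric(phi %*% se$coef)
  fit_c <- as.numeric(phi %*% sc$coef)
  res <- c((fit_e - series$epsilon_obs) * weights$epsilon,
           (fit_c - series$delta_epsilon_obs) * weights$delta_epsilon)
  list(residuals = res, params = params,
       eps = se$coef, deps = sc$coef,
       fitted = list(epsilon = fit_e, delta_epsilon = fit_c),
       rss = c(epsilon = sum((fit_e - series$epsilon_obs)^2),
               delta_epsilon = sum((fit_c - series$delta_epsilon_obs)^2)),
       nonneg_flagged = se$flagged)
}

# data-driven starting guess: elongation constant from the concentration at
# the half-rise of the absorption channel, dimerization one decade above
# the inverse median concentration, nucleation at sigma = 1e-4.
.default_init <- function(series) {
  cs <- series$c_total_M
  y <- series$epsilon_obs
  half <- min(y) + 0.5 * (max(y) - min(y))
  above <- which(y >= half)
  c_half <- if (length(above)) cs[min(above)] else stats::median(cs)
  K_J2 <- 1 / c_half
  thermo_params(K_J1 = 1 / stats::median(cs),
                K_N = 1e-4 * K_J2, K_J2 = K_J2)
}

#' Fit equilibrium constants to a concentration series
#'
#' Estimates the three equilibrium constants (off-pathway dimerization,
#' nucleation, elongation) and the six per-species observable coefficients
#' from a concentration-dependent series of epsilon and delta-epsilon
#' observations. The constants are searched in log10 space by
#' Levenberg-Marquardt least squares; at every evaluation the linearly
#' entering coefficients are solved by per-channel linear least squares
#' (variable projection), with non-negativity enforced on the absorptivity
#' coefficients by an active set (flagged when triggered). Each channel's
#' residuals are weighted per point by the inverse observed magnitude by
#' default (see `weighting` in [fit_options()]) — the statistically
#' appropriate weights when the dominant error is multiplicative — and each
#' channel is normalized so both contribute comparably. Several jittered starts guard against the
#' multimodality of the biphasic objective.
#'
#' @param series Data frame with columns `c_total_M`, `epsilon_obs`,
#'   `delta_epsilon_obs`; at least 8 distinct concentrations spanning at
#'   least 1.5 decades.
#' @param init Optional [thermo_params()] starting guess; defaults to a
#'   data-driven heuristic.
#' @param options A [fit_options()] list.
#' @param T_K Temperature attached to the estimated parameters, K.
#' @return Object of class `thermo_fit`: estimated `params` and `coeffs`,
#'   per-channel `rss`, `converged`, `iterations`, `n_starts`, the
#'   objective of every start, optional `bootstrap` quantiles, and the
#'   `seed` used.
#' @export
fit_concentration_series <- function(series, init = NULL,
                                     options = fit_options(),
                                     T_K = 293) {
  need <- c("c_total_M", "epsilon_obs", "delta_epsilon_obs")
  if (!all(need %in% names(series)))
    stop("series must have columns c_total_M, epsilon_obs, delta_epsilon_obs",
         call. = FALSE)
  lambda_A <- attr(series, "lambda_A_nm") %||% NA_real_
  lambda_C <- attr(series, "lambda_C_nm") %||% NA_real_
  series <- series[order(series$c_total_M), need]
  cs <- unique(series$c_total_M)
  if (length(cs) < 8L)
    stop("need at least 8 distinct concentrations", call. = FALSE)
  if (log10(max(cs) / min(cs)) < 1.5)
    stop("concentration series must span at least 1.5 decades", call. = FALSE)
  if (diff(range(series$epsilon_obs)) <= 0 ||
      diff(range(series$delta_epsilon_obs)) <= 0)
    stop("non-identifiable series: an observable channel is constant",
         call. = FALSE)
  weights <- list(
    epsilon = .channel_weights(series$epsilon_obs, options$weighting),
    delta_epsilon = .channel_weights(series$delta_epsilon_obs,
                                     options$weighting))
  heur <- .default_init(series)
  p_heur <- log10(c(heur$K_J1, heur$K_N, heur$K_J2))
  if (is.null(init)) init <- heur
  stopifnot(inherits(init, "thermo_params"))
  p0 <- log10(c(init$K_J1, init$K_N, init$K_J2))

  start_pars <- local({
    set.seed(options$seed)
    j <- matrix(stats::runif(3L * options$n_starts, -1, 1) *
                  options$start_jitter_decades,
                nrow = options$n_starts)
    j[1L, ] <- 0  # first start is the unjittered guess
    pars <- lapply(seq_len(options$n_starts), function(i) p0 + j[i, ])
    # a user-supplied guess can sit in a poor basin; always keep the
    # data-driven heuristic in the start set as well
    if (max(abs(p0 - p_heur)) > 1e-12) pars <- c(pars, list(p_heur))
    pars
  })

  run_start <- function(p_start) {
    fit <- minpack.lm::nls.lm(
      par = pmin(pmax(p_start, options$lower_log10), options$upper_log10),
      lower = options$lower_log10, upper = options$upper_log10,
      fn = function(p) .varpro_eval(p, series, weights, T_K,
                                    options$pin_monomer)$residuals,
      control = minpack.lm::nls.lm.control(
        maxiter = options$maxiter, ftol = 1e-15, ptol = 1e-13))
    list(par = fit$par, obj = fit$deviance, info = fit$info,
         niter = fit$niter)
  }

  starts <- lapply(start_pars, run_start)
  objs <- vapply(starts, `[[`, numeric(1), "obj")
  best_obj <- min(objs)
  cand <- which(objs <= best_obj * (1 + 1e-9) + 1e-300)
  if (length(cand) > 1L) {  # tie: smallest nucleation constant wins
    kn <- vapply(cand, function(i) starts[[i]]$par[2], numeric(1))
    cand <- cand[which.min(kn)]
  }
  best <- starts[[cand[1L]]]

  ev <- .varpro_eval(best$par, series, weights, T_K, options$pin_monomer)
  sp <- c("monomer", "J1", "J2")
  coeffs <- observable_coefficients(
    eps = stats::setNames(ev$eps, sp),
    deps = stats::setNames(ev$deps, sp),
    lambda_A_nm = if (is.na(lambda_A)) 750 else lambda_A,
    lambda_C_nm = if (is.na(lambda_C)) 746 else lambda_C)

  out <- structure(list(
    params = ev$params,
    coeffs = coeffs,
    rss = ev$rss,
    objective = best$obj,
    converged = best$info %in% c(1L, 2L, 3L),
    iterations = best$niter,
    n_starts = options$n_starts,
    start_objectives = objs,
    nonneg_flagged = ev$nonneg_flagged,
    seed = options$seed,
    bootstrap = NULL), class = "thermo_fit")

  if (options$n_boot > 0L)
    out$bootstrap <- .residual_bootstrap(out, series, weights, T_K, options)
  out
}

# residual bootstrap: resample per-channel residuals, refit from the best
# estimate, summarize constants by quantiles. The study itself reports no
# uncertainties; these intervals are an addition of this package.
.residual_bootstrap <- function(fit, series, weights, T_K, options) {
  p_hat <- log10(c(fit$params$K_J1, fit$params$K_N, fit$params$K_J2))
  ev <- .varpro_eval(p_hat, series, weights, T_K, options$pin_monomer)
  n <- nrow(series)
  fit_e <- ev$fitted$epsilon
  fit_c <- ev$fitted$delta_epsilon
  res_e <- fit_e - series$epsilon_obs
  res_c <- fit_c - series$delta_epsilon_obs
  set.seed(options$seed + 1L)
  draws <- matrix(NA_real_, nrow = options$n_boot, ncol = 3,
                  dimnames = list(NULL, c("K_J1", "K_N", "K_J2")))
  for (b in seq_len(options$n_boot)) {
    bs <- series
    bs$epsilon_obs <- fit_e - sample(res_e, n, replace = TRUE)
    bs$delta_epsilon_obs <- fit_c - sample(res_c, n, replace = TRUE)
    bfit <- minpack.lm::nls.lm(
      par = p_hat, lower = options$lower_log10, upper = options$upper_log10,
      fn = function(p) .varpro_eval(p, bs, weights, T_K,
                                    options$pin_monomer)$residuals,
      control = minpack.lm::nls.lm.control(maxiter = 100L))
    draws[b, ] <- 10^bfit$par
  }
  apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("<thermo_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("(%d LM iterations, %d starts)\n", x$iterations, x$n_starts))
  print(x$params)
  cat(sprintf("  RSS: epsilon %.4g, delta-epsilon %.4g\n",
              x$rss[1], x$rss[2]))
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap quantiles (2.5/50/97.5%):\n")
    print(x$bootstrap)
  }
  invisible(x)
}
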