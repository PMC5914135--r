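#' Equilibrium constants of the competing-pathway model
#'
#' Parameter set of the competing-pathway equilibrium: monomers either form
#' an off-pathway dimer (association constant `K_J1`) or polymerize
#' cooperatively into helical stacks through an unfavourable nucleation
#' step (`K_N`, formation of the dimeric nucleus) followed by isodesmic
#' elongation (`K_J2` for every further monomer addition) — the K2-K
#' nucleation-elongation scheme. The cooperativity parameter is
#' `sigma = K_N / K_J2`; `sigma << 1` gives a sharp polymerization onset
#' near the elongation concentration `1/K_J2`.
#'
#' @param K_J1 Off-pathway dimerization constant, M^-1 (> 0).
#' @param K_N Nucleation binding constant, M^-1 (> 0).
#' @param K_J2 Elongation binding constant, M^-1 (> 0).
#' @param T_K Absolute temperature, K (> 0). Default 293 K.
#' @return A `thermo_params` object.
#' @examples
#' p <- thermo_params(K_J1 = 1.3e4, K_N = 2.4e-2, K_J2 = 1.0e5)
#' cooperativity(p)
#' @export
thermo_params <- function(K_J1, K_N, K_J2, T_K = 293) {
  vals <- c(K_J1 = K_J1, K_N = K_N, K_J2 = K_J2, T_K = T_K)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all equilibrium constants and T_K must be positive and finite",
         call. = FALSE)
  structure(list(K_J1 = K_J1, K_N = K_N, K_J2 = K_J2, T_K = T_K),
            class = "thermo_params")
}

#' @rdname thermo_params
#' @param params A `thermo_params` object.
#' @export
cooperativity <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  params$K_N / params$K_J2
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> K_J1 = %.4g M^-1, K_N = %.4g M^-1, K_J2 = %.4g M^-1, T = %g K (sigma = %.3g)\n",
    x$K_J1, x$K_N, x$K_J2, x$T_K, cooperativity(x)))
  invisible(x)
}

# total concentration implied by a free monomer concentration m:
#   c_T(m) = m + 2 K_J1 m^2 + K_N m^2 (2 - K_J2 m) / (1 - K_J2 m)^2
# (monomer + off-pathway dimer mass + closed-form mass of all stacks i >= 2)
.mass_balance_total <- function(m, params) {
  x <- params$K_J2 * m
  m + 2 * params$K_J1 * m^2 +
    params$K_N * m^2 * (2 - x) / (1 - x)^2
}

# d c_T / d m, used for the Newton polish
.mass_balance_deriv <- function(m, params) {
  x <- params$K_J2 * m
  1 + 4 * params$K_J1 * m +
    params$K_N * (2 * m * (2 - x) / (1 - x)^2 +
                    params$K_J2 * m^2 * (3 - x) / (1 - x)^3)
}

#' Free monomer concentration at a total concentration
#'
#' Solves the mass balance
#' \deqn{c_T = m + 2 K_{J1} m^2 + K_N m^2 (2 - K_{J2} m)/(1 - K_{J2} m)^2}
#' for the free monomer concentration m. The right-hand side is strictly
#' increasing in m on (0, 1/K_J2), so the root is unique; it is bracketed
#' in (0, min(c_T, 1/K_J2)), located with Brent's method, and polished with
#' safeguarded Newton steps until the relative residual is at most 1e-10.
#'
#' @param params A [thermo_params()].
#' @param c_T Total concentration(s) in monomer units, M (> 0). Vectorized.
#' @return Free monomer concentration(s), M.
#' @export
free_monomer <- function(params, c_T) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(c_T)) || any(c_T <= 0))
    stop("c_T must be positive and finite", call. = FALSE)
  vapply(c_T, .free_monomer1, numeric(1), params = params)
}

.free_monomer1 <- function(c_T, params) {
  f <- function(m) .mass_balance_total(m, params) - c_T
  upper <- min(c_T, (1 - 1e-12) / params$K_J2)
  f_up <- f(upper)
  if (!is.finite(f_up)) {  # back off from the elongation pole
    for (eps in 10^seq(-11, -6)) {
      upper <- min(c_T, (1 - eps) / params$K_J2)
      f_up <- f(upper)
      if (is.finite(f_up)) break
    }
  }
  if (f_up < 0) {
    # root within machine resolution of 1/K_J2: widen to the last
    # representable m below the pole
    up2 <- min(c_T, (1 - .Machine$double.eps) / params$K_J2)
    f_up2 <- f(up2)
    if (up2 > upper && is.finite(f_up2) && f_up2 >= 0) {
      upper <- up2
      f_up <- f_up2
    } else {
      return(up2)
    }
  }
  r <- stats::uniroot(f, lower = 0, upper = upper,
                      f.lower = -c_T, f.upper = f_up,
                      tol = .Machine$double.eps * upper, maxiter = 200L)
  m <- r$root
  # Newton polish with bracket safeguard; stop when the relative residual
  # meets the contract or the bracket collapses to machine resolution in m
  # (the balance can be too steep near K_J2*m -> 1 for the residual test)
  lo <- 0; hi <- upper
  for (it in 1:60) {
    res <- f(m)
    if (abs(res) <= 1e-10 * c_T) break
    if (res > 0) hi <- m else lo <- m
    if (hi - lo <= 4 * .Machine$double.eps * hi) break
    step <- res / .mass_balance_deriv(m, params)
    m2 <- m - step
    if (!is.finite(m2) || m2 <= lo || m2 >= hi) m2 <- (lo + hi) / 2
    m <- m2
  }
  if (abs(f(m)) > 1e-10 * c_T && hi - lo > 4 * .Machine$double.eps * hi)
    stop(sprintf(
      "mass-balance root not converged at c_T = %.3g M (bracket [%.3g, %.3g], residual %.3g)",
      c_T, lo, hi, f(m) / c_T), call. = FALSE)
  m
}

#' Species distribution at total concentration(s)
#'
#' Partitions the total monomer concentration into free monomer,
#' off-pathway dimer and on-pathway polymer mass fractions, and reports the
#' number-average degree of polymerization of the stacks,
#' `dp_n = (2 - x)/(1 - x)` with `x = K_J2 * m`.
#'
#' @inheritParams free_monomer
#' @return A data frame of class `species_distribution` with columns
#'   `c_T`, `m`, `phi_mono`, `phi_dimer`, `phi_polymer`, `dp_n`.
#' @export
species_distribution <- function(params, c_T) {
  m <- free_monomer(params, c_T)
  phi_mono <- m / c_T
  phi_dimer <- 2 * params$K_J1 * m^2 / c_T
  phi_polymer <- pmax(0, 1 - phi_mono - phi_dimer)
  x <- params$K_J2 * m
  out <- data.frame(c_T = c_T, m = m, phi_mono = phi_mono,
                    phi_dimer = phi_dimer, phi_polymer = phi_polymer,
                    dp_n = (2 - x) / (1 - x))
  class(out) <- c("species_distribution", "data.frame")
  out
}

#' Truncated-series oracle for the mass balance
#'
#' Direct evaluation of the total concentration as a finite sum over
#' oligomer sizes,
#' \deqn{m + 2 K_{J1} m^2 + \sum_{i=2}^{i_{max}} i K_N K_{J2}^{i-2} m^i,}
#' used as an independent check of the closed-form mass balance. The final
#' term is reported so callers can bound the truncation tail.
#'
#' @param params A [thermo_params()].
#' @param m Free monomer concentration, M; requires `K_J2 * m < 1`.
#' @param i_max Largest stack size included (>= 2).
#' @return List with `total` (M) and `last_term` (M).
#' @export
truncated_sum_oracle <- function(params, m, i_max) {
  stopifnot(inherits(params, "thermo_params"),
            is.numeric(m), length(m) == 1L, m > 0,
            i_max >= 2)
  x <- params$K_J2 * m
  if (x >= 1)
    stop("series diverges: K_J2 * m >= 1", call. = FALSE)
  i <- 2:i_max
  terms <- i * params$K_N * m^2 * x^(i - 2)
  list(total = m + 2 * params$K_J1 * m^2 + sum(terms),
       last_term = terms[length(terms)])
}

#' Per-species observable coefficients
#'
#' Per-monomer molar absorptivity at the absorption probe wavelength and
#' per-monomer molar CD at the CD probe wavelength, for each of the three
#' species. These map a species distribution onto the observed epsilon and
#' delta-epsilon of the mixture.
#'
#' @param eps Named numeric of length 3 (`monomer`, `J1`, `J2`): epsilon at
#'   `lambda_A_nm`, each >= 0.
#' @param deps Named numeric of length 3: delta-epsilon at `lambda_C_nm`
#'   (any sign).
#' @param lambda_A_nm,lambda_C_nm Probe wavelengths, nm (> 0).
#' @return An `observable_coefficients` object.
#' @export
observable_coefficients <- function(eps, deps, lambda_A_nm, lambda_C_nm) {
  sp <- c("monomer", "J1", "J2")
  eps <- eps[sp]; deps <- deps[sp]
  if (any(is.na(eps)) || any(is.na(deps)))
    stop("eps and deps must be named vectors with entries monomer, J1, J2",
         call. = FALSE)
  if (any(eps < 0)) stop("epsilon coefficients must be >= 0", call. = FALSE)
  if (lambda_A_nm <= 0 || lambda_C_nm <= 0)
    stop("probe wavelengths must be positive", call. = FALSE)
  structure(list(eps = eps, deps = deps,
                 lambda_A_nm = lambda_A_nm, lambda_C_nm = lambda_C_nm),
            class = "observable_coefficients")
}

#' @export
print.observable_coefficients <- function(x, ...) {
  cat(sprintf("<observable_coefficients> epsilon @ %g nm, delta-epsilon @ %g nm\n",
              x$lambda_A_nm, x$lambda_C_nm))
  print(rbind(eps = x$eps, deps = x$deps))
  invisible(x)
}

#' Predicted concentration series of the observables
#'
#' Per-monomer observables of the equilibrated mixture over a grid of total
#' concentrations: each observable is the mass-fraction-weighted
#' (convex) combination of the three species coefficients.
#'
#' @param params A [thermo_params()].
#' @param coeffs An [observable_coefficients()].
#' @param concentrations Positive total concentrations, M.
#' @return Data frame with columns `c_total_M`, `epsilon_obs`,
#'   `delta_epsilon_obs`; probe wavelengths kept as attributes
#'   `lambda_A_nm`, `lambda_C_nm`.
#' @export
observable_series <- function(params, coeffs, concentrations) {
  stopifnot(inherits(coeffs, "observable_coefficients"))
  d <- species_distribution(params, concentrations)
  phi <- as.matrix(d[, c("phi_mono", "phi_dimer", "phi_polymer")])
  out <- data.frame(
    c_total_M = concentrations,
    epsilon_obs = as.numeric(phi %*% coeffs$eps),
    delta_epsilon_obs = as.numeric(phi %*% coeffs$deps))
  attr(out, "lambda_A_nm") <- coeffs$lambda_A_nm
  attr(out, "lambda_C_nm") <- coeffs$lambda_C_nm
  out
}

#' Elongation concentration
#'
#' The concentration scale `1/K_J2` above which extended stacks accumulate
#' in a cooperative (sigma << 1) system; diagnostic for the sharp onset of
#' fiber growth.
#'
#' @param params A [thermo_params()].
#' @return Concentration in M.
#' @export
elongation_concentration <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  1 / params$K_J2
}
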