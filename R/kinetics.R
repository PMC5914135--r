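#' Anisotropy-factor time course
#'
#' A sampled g(t) trace monitoring the transformation of the kinetically
#' trapped aggregate into the equilibrated fiber state at one solvent
#' condition, with the condition metadata the rate table needs.
#'
#' @param time_h Non-negative, strictly increasing sampling times in hours.
#' @param g Anisotropy factor at each time (dimensionless).
#' @param condition MeOH:water volume-ratio label, e.g. `"30:70"`.
#' @param c_T Total concentration, M.
#' @param T_K Temperature, K.
#' @return A `kinetic_trace`.
#' @export
kinetic_trace <- function(time_h, g, condition = NA_character_,
                          c_T = NA_real_, T_K = NA_real_) {
  time_h <- as.numeric(time_h); g <- as.numeric(g)
  if (length(time_h) != length(g))
    stop("time_h and g lengths differ", call. = FALSE)
  if (length(time_h) < 4L)
    stop("a trace needs at least 4 samples for rate estimation",
         call. = FALSE)
  if (!all(is.finite(time_h)) || any(time_h < 0) || any(diff(time_h) <= 0))
    stop("times must be finite, non-negative and strictly increasing",
         call. = FALSE)
  if (!all(is.finite(g))) stop("g values must be finite", call. = FALSE)
  structure(list(time_h = time_h, g = g, condition = condition,
                 c_T = c_T, T_K = T_K),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "<kinetic_trace> %s: %d samples over %.2f h, g %.3g -> %.3g\n",
    x$condition, length(x$time_h), max(x$time_h) - min(x$time_h),
    x$g[1], x$g[length(x$g)]))
  invisible(x)
}

# water volume percentage from a "MeOH:water" label like "30:70"
.water_percent <- function(condition) {
  parts <- strsplit(as.character(condition), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) return(NA_real_)
    as.numeric(p[2]) / (as.numeric(p[1]) + as.numeric(p[2])) * 100
  }, numeric(1))
}

#' Initial transformation rate d(g)/dt
#'
#' Estimates the initial rate of a g(t) trace by least squares over the
#' initial window: all leading samples whose g lies within the first 25% of
#' the total observed change (never fewer than 3). Within that window a
#' quadratic in time is fitted and its derivative at the first sample is
#' reported, which cancels the first-order curvature bias an exponential
#' approach to equilibrium would otherwise impose on a straight-line slope
#' (about 13% low over a 25%-of-change window, versus under 1% for the
#' curvature-corrected estimate).
#'
#' @param trace A [kinetic_trace()].
#' @return A `rate_estimate`: `rate` (h^-1, signed as the trace moves),
#'   `window` (indices used), `goodness` (residual standard error of the
#'   windowed fit) and `monotone_warning` (TRUE when the initial segment is
#'   not monotone on average).
#' @export
initial_rate <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time_h; g <- trace$g
  total <- abs(g[length(g)] - g[1])
  if (total == 0) {
    in_win <- rep(TRUE, length(g))
  } else {
    in_win <- abs(g - g[1]) <= 0.25 * total
  }
  # leading contiguous run, at least 3 samples
  last <- which(!in_win)[1]
  n_win <- if (is.na(last)) length(g) else last - 1L
  n_win <- max(n_win, 3L)
  if (n_win > length(g))
    stop("fewer than 3 usable samples in the initial window", call. = FALSE)
  w <- seq_len(n_win)
  tw <- t[w] - t[1]
  fit <- stats::lm(g[w] ~ tw + I(tw^2))
  rate <- unname(stats::coef(fit)[["tw"]])
  rse <- sqrt(sum(stats::resid(fit)^2) / max(1L, stats::df.residual(fit)))
  dg <- diff(g[w])
  monotone_warning <- total > 0 && length(dg) > 0 &&
    abs(sum(dg)) < 0.5 * sum(abs(dg))
  structure(list(rate = rate, window = w, goodness = rse,
                 monotone_warning = monotone_warning),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> d(g)/dt = %.4g h^-1 over %d samples (RSE %.2g)%s\n",
              x$rate, length(x$window), x$goodness,
              if (x$monotone_warning) " [non-monotone initial segment]" else ""))
  invisible(x)
}

#' Simulate an anisotropy-factor trace
#'
#' Single-exponential approach to equilibrium,
#' \deqn{g(t) = g_{start} + (g_{end} - g_{start}) (1 - e^{-kt}),}
#' parameterized by its initial rate: `k = initial_rate / |g_end - g_start|`,
#' so the analytic derivative at t = 0 equals `initial_rate` exactly. A
#' zero rate yields a constant trace at `g_start` (a fully trapped state).
#'
#' @param g_start,g_end Initial and asymptotic g values.
#' @param initial_rate Initial |d(g)/dt| in h^-1 (>= 0).
#' @param time_h Sampling times in hours.
#' @param lag_h Optional lag before the transformation starts (hook for
#'   off-pathway depletion lag phases); the trace is constant at `g_start`
#'   up to `lag_h`. Default 0.
#' @inheritParams kinetic_trace
#' @return A [kinetic_trace()].
#' @export
simulate_trace <- function(g_start, g_end, initial_rate, time_h,
                           condition = NA_character_, c_T = NA_real_,
                           T_K = NA_real_, lag_h = 0) {
  if (initial_rate < 0) stop("initial_rate must be >= 0", call. = FALSE)
  if (initial_rate > 0 && g_end == g_start)
    stop("g_end equals g_start but the rate is nonzero", call. = FALSE)
  if (initial_rate == 0) {
    g <- rep(g_start, length(time_h))
  } else {
    k <- initial_rate / abs(g_end - g_start)
    ts <- pmax(0, time_h - lag_h)
    g <- g_start + (g_end - g_start) * (1 - exp(-k * ts))
  }
  kinetic_trace(time_h, g, condition = condition, c_T = c_T, T_K = T_K)
}

#' Rate table across solvent conditions
#'
#' Initial-rate estimates for a list of traces, one row per trace, ordered
#' by increasing water content of the solvent mixture.
#'
#' @param traces List of [kinetic_trace()] objects with distinct condition
#'   labels.
#' @return Data frame with columns `condition`, `water_pct`, `rate_per_h`,
#'   `goodness`.
#' @export
rate_table <- function(traces) {
  if (length(traces) == 0L)
    return(data.frame(condition = character(), water_pct = numeric(),
                      rate_per_h = numeric(), goodness = numeric()))
  conds <- vapply(traces, function(tr) as.character(tr$condition),
                  character(1))
  if (anyDuplicated(conds))
    stop(sprintf("duplicate condition labels: %s",
                 paste(unique(conds[duplicated(conds)]), collapse = ", ")),
         call. = FALSE)
  est <- lapply(traces, initial_rate)
  out <- data.frame(
    condition = conds,
    water_pct = .water_percent(conds),
    rate_per_h = vapply(est, `[[`, numeric(1), "rate"),
    goodness = vapply(est, `[[`, numeric(1), "goodness"))
  out[order(out$water_pct), , drop = FALSE]
}
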