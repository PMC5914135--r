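#' Dye spectrum on a wavelength grid
#'
#' Container for a per-monomer absorption spectrum with an optional circular
#' dichroism (CD) channel. Both channels are stored on a common, strictly
#' increasing wavelength grid in nm; `epsilon` is the molar absorptivity
#' (M^-1 cm^-1, per monomer) and `delta_epsilon` the molar CD on the same
#' per-monomer convention.
#'
#' @param wavelength_nm Numeric vector, strictly increasing, all > 0 (nm).
#' @param epsilon Numeric vector, same length, finite and >= 0.
#' @param delta_epsilon Optional numeric vector, same length, finite
#'   (any sign). `NULL` means the spectrum has no CD channel.
#' @return An object of class `dye_spectrum`.
#' @examples
#' s <- dye_spectrum(400:500, rep(1, 101))
#' has_cd_channel(s)
#' @export
dye_spectrum <- function(wavelength_nm, epsilon, delta_epsilon = NULL) {
  wavelength_nm <- as.numeric(wavelength_nm)
  epsilon <- as.numeric(epsilon)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two grid points", call. = FALSE)
  if (length(epsilon) != length(wavelength_nm))
    stop("epsilon and wavelength_nm lengths differ", call. = FALSE)
  if (!all(is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    stop("wavelengths must be finite and positive", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(epsilon)) || any(epsilon < 0))
    stop("epsilon must be finite and non-negative", call. = FALSE)
  if (!is.null(delta_epsilon)) {
    delta_epsilon <- as.numeric(delta_epsilon)
    if (length(delta_epsilon) != length(wavelength_nm))
      stop("delta_epsilon and wavelength_nm lengths differ", call. = FALSE)
    if (!all(is.finite(delta_epsilon)))
      stop("delta_epsilon must be finite", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, epsilon = epsilon,
         delta_epsilon = delta_epsilon),
    class = "dye_spectrum"
  )
}

#' @rdname dye_spectrum
#' @param x A `dye_spectrum`.
#' @export
has_cd_channel <- function(x) {
  stopifnot(inherits(x, "dye_spectrum"))
  !is.null(x$delta_epsilon)
}

#' @export
print.dye_spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf(
    "<dye_spectrum> %d points, %.1f-%.1f nm, CD channel: %s\n",
    length(x$wavelength_nm), rng[1], rng[2],
    if (has_cd_channel(x)) "yes" else "no"))
  invisible(x)
}

#' Convert wavelength to wavenumber (and back)
#'
#' The conversion `nu = 1e7 / lambda` maps nm to cm^-1 and is its own
#' inverse, so the same function converts in either direction.
#'
#' @param wavelength_nm Positive numeric vector (nm, or cm^-1 for the
#'   reverse direction).
#' @return Wavenumber in cm^-1 (or wavelength in nm).
#' @examples
#' nm_to_wavenumber(1000)  # 10000 cm^-1
#' @export
nm_to_wavenumber <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm <= 0))
    stop("wavelength must be finite and positive", call. = FALSE)
  1e7 / wavelength_nm
}

# linear interpolation of one channel at a query wavelength
.interp_channel <- function(spectrum, channel, wavelength_nm) {
  w <- spectrum$wavelength_nm
  if (wavelength_nm < w[1] || wavelength_nm > w[length(w)])
    stop(sprintf("wavelength %.2f nm outside grid range [%.2f, %.2f]",
                 wavelength_nm, w[1], w[length(w)]), call. = FALSE)
  stats::approx(w, spectrum[[channel]], xout = wavelength_nm)$y
}

#' Anisotropy factor g at a wavelength
#'
#' The anisotropy (dissymmetry) factor g = delta_epsilon / epsilon,
#' evaluated at a query wavelength with linear interpolation of both
#' channels. g is a dimensionless measure of chiral excitonic order and is
#' invariant under rescaling of both channels by the same factor.
#'
#' @param spectrum A `dye_spectrum` with a CD channel.
#' @param wavelength_nm Query wavelength inside the grid range.
#' @return g (dimensionless).
#' @export
anisotropy_factor <- function(spectrum, wavelength_nm) {
  stopifnot(inherits(spectrum, "dye_spectrum"))
  if (!has_cd_channel(spectrum))
    stop("spectrum has no CD channel; g = delta_epsilon/epsilon is undefined",
         call. = FALSE)
  eps <- .interp_channel(spectrum, "epsilon", wavelength_nm)
  if (eps == 0)
    stop(sprintf("epsilon is zero at %.2f nm; g undefined", wavelength_nm),
         call. = FALSE)
  .interp_channel(spectrum, "delta_epsilon", wavelength_nm) / eps
}

# parabolic (3-point) peak refinement; returns list(x, y) at the vertex.
# x must be the abscissa values at i-1, i, i+1 (any monotone axis).
.parabolic_vertex <- function(x, y) {
  d1 <- (y[3] - y[1]) / 2
  d2 <- y[1] - 2 * y[2] + y[3]
  if (d2 >= 0) return(list(x = x[2], y = y[2]))  # degenerate: keep grid max
  # offset in index units, mapped onto the (locally ~linear) axis
  h <- -d1 / d2
  xv <- x[2] + h * (x[3] - x[1]) / 2
  yv <- y[2] - d1^2 / (2 * d2)
  list(x = xv, y = yv)
}

# locate the single interior maximum of epsilon inside a window
.window_peak <- function(spectrum, window_nm) {
  stopifnot(inherits(spectrum, "dye_spectrum"), length(window_nm) == 2L)
  w <- spectrum$wavelength_nm
  idx <- which(w >= min(window_nm) & w <= max(window_nm))
  if (length(idx) < 3L)
    stop("window contains fewer than 3 grid points", call. = FALSE)
  e <- spectrum$epsilon[idx]
  i <- which.max(e)
  if (i == 1L || i == length(idx))
    stop("no interior maximum in window (signal monotone or peak at edge)",
         call. = FALSE)
  j <- idx[i]
  list(idx = idx, j = j, i = i)
}

#' Peak position inside a window
#'
#' Locates the absorption maximum inside a wavelength window with
#' sub-gridpoint accuracy (3-point parabolic interpolation around the grid
#' maximum).
#'
#' @param spectrum A `dye_spectrum`.
#' @param window_nm Length-2 numeric, the window in nm. Must contain exactly
#'   one local maximum of epsilon.
#' @return Peak wavelength in nm.
#' @export
peak_position <- function(spectrum, window_nm) {
  p <- .window_peak(spectrum, window_nm)
  w <- spectrum$wavelength_nm
  .parabolic_vertex(w[(p$j - 1):(p$j + 1)],
                    spectrum$epsilon[(p$j - 1):(p$j + 1)])$x
}

#' Bathochromic band shift between two spectra
#'
#' Difference of the peak positions of two spectra inside the same window;
#' positive values are bathochromic (red) shifts of `spec_b` relative to
#' `spec_a`.
#'
#' @param spec_a,spec_b `dye_spectrum` objects.
#' @param window_nm Length-2 analysis window in nm.
#' @return Shift in nm.
#' @export
band_shift <- function(spec_a, spec_b, window_nm) {
  peak_position(spec_b, window_nm) - peak_position(spec_a, window_nm)
}

#' Band width (FWHM) in wavenumbers
#'
#' Full width at half maximum of the single absorption band inside a
#' wavelength window, measured on the wavenumber (cm^-1) axis: the peak is
#' refined by parabolic interpolation, and the two half-maximum crossings
#' are found by linear interpolation of epsilon against wavenumber.
#'
#' @inheritParams peak_position
#' @return FWHM in cm^-1.
#' @export
band_fwhm <- function(spectrum, window_nm) {
  p <- .window_peak(spectrum, window_nm)
  w <- spectrum$wavelength_nm
  e <- spectrum$epsilon
  vx <- .parabolic_vertex(nm_to_wavenumber(w[(p$j - 1):(p$j + 1)]),
                          e[(p$j - 1):(p$j + 1)])
  half <- vx$y / 2
  idx <- p$idx
  nu <- nm_to_wavenumber(w[idx])
  ei <- e[idx]
  i <- p$i
  cross <- function(ii, jj) {
    # linear interpolation of the half-max crossing between grid points ii, jj
    nu[ii] + (half - ei[ii]) * (nu[jj] - nu[ii]) / (ei[jj] - ei[ii])
  }
  # red side of the peak: increasing index = longer wavelength = lower nu
  red <- NA_real_
  for (ii in i:(length(idx) - 1L)) {
    if (ei[ii] >= half && ei[ii + 1L] < half) { red <- cross(ii, ii + 1L); break }
  }
  if (is.na(red))
    stop("band truncated by window on the long-wavelength (red) side",
         call. = FALSE)
  blue <- NA_real_
  for (ii in i:2L) {
    if (ei[ii] >= half && ei[ii - 1L] < half) { blue <- cross(ii, ii - 1L); break }
  }
  if (is.na(blue))
    stop("band truncated by window on the short-wavelength (blue) side",
         call. = FALSE)
  abs(blue - red)
}
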