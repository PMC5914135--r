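#' Gaussian band on the energy axis
#'
#' One electronic band modelled as a Gaussian on the wavenumber (cm^-1)
#' axis — the physical lineshape convention, and the axis on which the
#' widths of chlorin Qy bands are conventionally quoted. The amplitude is
#' attained exactly at the band center and may be negative for CD lobes.
#'
#' @param center_nm Band center in nm (> 0).
#' @param amplitude Peak value in M^-1 cm^-1 (signed for CD lobes).
#' @param fwhm_cm Full width at half maximum in cm^-1 (> 0).
#' @return A `gaussian_band`.
#' @export
gaussian_band <- function(center_nm, amplitude, fwhm_cm) {
  stopifnot(is.numeric(center_nm), length(center_nm) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(fwhm_cm), length(fwhm_cm) == 1L)
  if (!is.finite(center_nm) || center_nm <= 0)
    stop("band center must be positive", call. = FALSE)
  if (!is.finite(fwhm_cm) || fwhm_cm <= 0)
    stop("band fwhm must be positive", call. = FALSE)
  structure(list(center_nm = center_nm, amplitude = amplitude,
                 fwhm_cm = fwhm_cm),
            class = "gaussian_band")
}

# evaluate one band on a wavelength grid (Gaussian in wavenumber)
.eval_band <- function(band, wavelength_nm) {
  nu <- nm_to_wavenumber(wavelength_nm)
  nu0 <- nm_to_wavenumber(band$center_nm)
  band$amplitude * exp(-4 * log(2) * ((nu - nu0) / band$fwhm_cm)^2)
}

.eval_bands <- function(bands, wavelength_nm) {
  out <- numeric(length(wavelength_nm))
  for (b in bands) out <- out + .eval_band(b, wavelength_nm)
  out
}

#' Spectral model of one species
#'
#' Gaussian-band description of the absorption (and, for aggregates, CD)
#' spectrum of one of the three species of the self-assembly: the dissolved
#' monomer, the kinetically trapped dimer/nanoparticle state (J1), or the
#' equilibrated helical J-aggregate fiber (J2). A bisignate exciton couplet
#' is modelled as one positive and one negative CD lobe.
#'
#' @param label One of `"monomer"`, `"J1"`, `"J2"`.
#' @param absorption_bands List of [gaussian_band()] (at least one; all
#'   amplitudes > 0).
#' @param cd_bands List of [gaussian_band()] for the CD channel; empty for
#'   an achiral/CD-silent species. For J1/J2 exactly one positive and one
#'   negative lobe are required (an exciton couplet).
#' @return A `species_model`.
#' @export
species_model <- function(label, absorption_bands, cd_bands = list()) {
  label <- match.arg(label, c("monomer", "J1", "J2"))
  if (inherits(absorption_bands, "gaussian_band"))
    absorption_bands <- list(absorption_bands)
  if (inherits(cd_bands, "gaussian_band")) cd_bands <- list(cd_bands)
  if (length(absorption_bands) < 1L)
    stop("at least one absorption band required", call. = FALSE)
  for (b in absorption_bands) {
    stopifnot(inherits(b, "gaussian_band"))
    if (b$amplitude <= 0)
      stop("absorption band amplitudes must be positive", call. = FALSE)
  }
  for (b in cd_bands) stopifnot(inherits(b, "gaussian_band"))
  if (label %in% c("J1", "J2")) {
    signs <- vapply(cd_bands, function(b) sign(b$amplitude), numeric(1))
    if (!(sum(signs > 0) == 1L && sum(signs < 0) == 1L))
      stop(sprintf(
        "%s requires a bisignate couplet: exactly one positive and one negative CD lobe",
        label), call. = FALSE)
  }
  structure(list(label = label, absorption_bands = absorption_bands,
                 cd_bands = cd_bands),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %s: %d absorption band(s), %d CD lobe(s)\n",
              x$label, length(x$absorption_bands), length(x$cd_bands)))
  invisible(x)
}

#' Default synthesis grid
#'
#' 350-850 nm at 0.5 nm spacing: covers the Soret band (428 nm) through the
#' red CD lobe of the fiber couplet (760 nm) with margin.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_grid <- function() seq(350, 850, by = 0.5)

#' Synthesize a spectrum from a species model
#'
#' Evaluates each channel as the sum of its Gaussian-in-energy bands on a
#' wavelength grid.
#'
#' @param model A [species_model()].
#' @param grid_nm Strictly increasing wavelength grid in nm.
#' @return A [dye_spectrum()]; the CD channel is present only if the model
#'   has CD lobes.
#' @export
synthesize_spectrum <- function(model, grid_nm = default_grid()) {
  stopifnot(inherits(model, "species_model"))
  if (length(grid_nm) == 0L) stop("empty wavelength grid", call. = FALSE)
  eps <- .eval_bands(model$absorption_bands, grid_nm)
  de <- if (length(model$cd_bands)) .eval_bands(model$cd_bands, grid_nm)
        else NULL
  dye_spectrum(grid_nm, eps, de)
}
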