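# shared fixtures built in code at test time

paper_constants <- function() thermo_params(K_J1 = 1.3e4, K_N = 2.4e-2,
                                            K_J2 = 1.0e5, T_K = 293)

# a single-Gaussian test spectrum on a fine grid
single_band_spectrum <- function(center_nm = 749, amplitude = 1,
                                 fwhm_cm = 510, grid = seq(600, 850, 0.5)) {
  synthesize_spectrum(
    species_model("monomer", gaussian_band(center_nm, amplitude, fwhm_cm)),
    grid)
}
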