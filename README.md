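# jaggpath

Thermodynamic and kinetic analysis of competing self-assembly pathways in
chlorin J-aggregation.

Zinc chlorin dyes — semi-synthetic models of the bacteriochlorophylls
that build chlorosomal light-harvesting antennae — can assemble along two
competing routes in methanol/water: a fast off-pathway route into
nanoparticles of antiparallel dimers (a kinetically trapped state with a
broad Qy band at 738 nm and weak bisignate CD), and a cooperative
on-pathway route through an unfavourable nucleation step into helical
J-aggregate fibers (narrow intensified Qy at 749 nm, strong CD couplet).
`jaggpath` is for spectroscopists and supramolecular chemists who want to
dissect such pathway complexity quantitatively from concentration- and
time-dependent UV/vis and CD data.

## The model

Species populations follow a competing-pathway mass balance: monomers
either dimerize off-pathway (constant K<sub>J1</sub>) or polymerize
cooperatively via the K₂–K nucleation–elongation scheme (nucleation
K<sub>N</sub> for the dimeric nucleus, elongation K<sub>J2</sub> for
every further addition). With x = K<sub>J2</sub>·m < 1 the total
concentration in monomer units is

> c<sub>T</sub> = m + 2 K<sub>J1</sub> m² + K<sub>N</sub> m² (2 − x)/(1 − x)²

and the measured per-monomer ε and Δε are mass-fraction-weighted
combinations of the three species coefficients. The three constants are
fitted to a concentration series by variable-projection nonlinear least
squares (constants in log₁₀ space via Levenberg–Marquardt, coefficients
by weighted linear least squares at each step), then converted to a Gibbs
energy landscape by ΔG° = −RT ln K. The trapped-to-equilibrated
transformation is quantified by the initial rate d(g)/dt of the
anisotropy factor g = Δε/ε at 745 nm. A calibrated synthetic-data
generator reproduces the published band positions, widths, g values,
constants and rates for round-trip validation; the methods vignette
(`vignettes/pathway-complexity.Rmd`) documents every modelling choice.

## Worked example

```r
library(jaggpath)

## spectral descriptors of the equilibrated fiber state
p <- znchl_presets()
s_mono <- synthesize_spectrum(p$monomer)
s_j2   <- synthesize_spectrum(p$J2)
peak_position(s_j2, c(690, 800))          # 749.0  (nm, Qy maximum)
band_fwhm(s_j2, c(690, 800))              # 510.0  (cm^-1)
band_shift(s_mono, s_j2, c(600, 800))     # 93.0   (nm, bathochromic)
anisotropy_factor(s_j2, 745)              # 0.0094 (dimensionless g)

## fit the competing-pathway model to a concentration series
series <- generate_concentration_series()   # noiseless reference dataset
fit <- fit_concentration_series(series)
fit
#> <thermo_fit> converged (11 LM iterations, 5 starts)
#> <thermo_params> K_J1 = 1.3e+04 M^-1, K_N = 0.024 M^-1, K_J2 = 1e+05 M^-1, T = 293 K (sigma = 2.4e-07)
#>   RSS: epsilon 1.163e-29, delta-epsilon 3.138e-34

energy_landscape(fit$params)
#>                    process       K dG_kJ_per_mol T_K rate_limiting
#> 1 off-pathway dimerization 1.3e+04    -23.076804 293         FALSE
#> 2               nucleation 2.4e-02      9.086063 293          TRUE
#> 3               elongation 1.0e+05    -28.047061 293         FALSE

## initial transformation rate in 30:70 MeOH/water
initial_rate(generate_kinetic_trace("30:70"))
#> <rate_estimate> d(g)/dt = 0.008539 h^-1 over 21 samples (RSE 9.4e-07)
```

The fit recovers the three equilibrium constants of the reference system
(1.3×10⁴, 2.4×10⁻², 1.0×10⁵ M⁻¹); the landscape shows nucleation as the
only positive — hence rate-limiting — step (+9.1 kJ/mol against −23.1 and
−28.0 kJ/mol for dimerization and elongation), which is why the
nanoparticle state is a kinetic trap. The estimated rate reproduces the
8.6×10⁻³ h⁻¹ preset of the 30:70 condition to within 1%.

A config-driven pipeline covers the same flow from the shell:

```sh
Rscript inst/cli/jaggpath.R generate --out run1 --seed 1729
Rscript inst/cli/jaggpath.R fit      --out run1
Rscript inst/cli/jaggpath.R kinetics --out run1
Rscript inst/cli/jaggpath.R report   --out run1
```

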