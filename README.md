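# icdbind

Analysis of drug–cyclodextrin inclusion complexes from induced circular
dichroism (ICD) and UV titrations, for spectroscopists and formulation
scientists who characterise host–guest binding of small hydrophobic drugs by
β-cyclodextrin (BCyD).

Cyclodextrins are chiral but have no chromophore above 220 nm; an achiral
guest with a chromophore shows no CD on its own. When the guest enters the
cyclodextrin cavity its chromophore becomes chirally perturbed and an ICD
band appears — direct evidence of complexation. `icdbind` covers the three
quantitative steps that follow:

1. **Stability constant.** The ICD signal is proportional only to the
   complex concentration, `ΔA(λ) = Δε_c(λ)·[HG]·l` (Beer–Lambert for
   circularly polarised light). Titrating host at constant guest gives a
   saturation curve whose curvature encodes the 1:1 association constant
   `K = [HG]/([H][G])`. The complex concentration is the physical root of
   the mass-action quadratic, and `K` is fitted either from a
   single-wavelength saturation curve (Levenberg–Marquardt, multi-start in
   log₁₀K) or globally across all wavelengths by variable projection, which
   also returns the complex-only CD band `Δε_c(λ)`.
2. **Two-state UV mixture.** The UV spectrum is the mole-fraction-weighted
   sum of free and complexed guest,
   `A(λ) = (ε_free·[G] + ε_complex·[HG])·l`, so the apparent UV maximum
   drifts toward the complex band as host is added (bathochromic shift),
   while the CD maximum — complex-only — stays put. The package models and
   tests this dichotomy.
3. **ICD band sign (Kodaka–Harata rules).** From complex coordinates the
   cavity frame is derived from the glycosidic (O4) oxygen ring
   (least-squares plane normal, oriented narrow→wide rim). For a chromophore
   inside the cavity, a transition dipole parallel to the axis predicts a
   positive ICD band and a perpendicular one negative; outside the cavity
   both reverse. The parallel/perpendicular dichotomy is operationalised by
   the orientation factor `(3cos²θ − 1)/2`, which changes sign at the magic
   angle 54.74°.

A synthetic-data module generates constant-guest titrations (Gaussian CD/UV
bands, 1:1 speciation, seeded noise) and toy cyclodextrin geometries, so the
whole pipeline runs and is tested without any instrument or
quantum-chemistry output.

## Worked example

Simulate a fenoprofen-like titration (guest 4×10⁻⁴ M, host ratios 0–20×,
true log₁₀K = 3.06, 1% noise) and re-estimate the constant globally:

```r
library(icdbind)

sim <- generate_titration(scenario(noise_frac = 0.01, seed = 42))
fit <- fit_k_global(sim$cd)
fit
#> 1:1 binding fit (global variable projection)
#>   K     = 1140 1/M  (stderr 11.5)
#>   logK  = 3.0569  (stderr 0.00436)
#>   residual rms = 5.639e-06 over 6 points; converged: TRUE
```

The fitted `logK = 3.057 ± 0.004` recovers the generating constant 3.06; the
`fitted_response` field holds the decomposed complex-only CD band, and
`autoplot(fit)` draws the saturation curve. Sign prediction on a toy complex
with the dipole tilted 20° off the cavity axis:

```r
host <- generate_toy_cyclodextrin()                 # 7-fold O4/O6/O2-O3 scaffold
g    <- generate_guest(c(0, 0, 0), dipole_theta = 20)
predict_complex_sign(list(host = host, guest = g$atoms), g$dipole)
#>   location theta orientation_factor predicted_sign
#>   inside      20              0.825 positive
```

A chromophore inside the cavity with its transition dipole locked within
~15–30° of the axis gives a positive ICD band, as observed for the
phenoxyphenyl drugs. The same operations are scriptable through the CLI
shim (`inst/cli/icdbind`): `simulate`, `smooth`, `fit`, `decompose`, `sign`,
all emitting JSON with the config and seed embedded.

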