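---
title: "Binding constants and sign rules from induced circular dichroism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding constants and sign rules from induced circular dichroism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdbind)
```

## The measurement model

An achiral guest with a chromophore gives no CD signal; its 1:1 inclusion
complex with a cyclodextrin does, because the chromophore is chirally
perturbed inside the chiral cavity. Two consequences drive everything in
this package:

* the induced CD (ICD) signal is proportional **only** to the complex
  concentration, $\Delta A(\lambda) = \Delta\varepsilon_c(\lambda)\,[HG]\,l$,
  so the CD channel is a pure complex spectrum and its band maximum does not
  move during a titration;
* the UV absorbance mixes both species,
  $A(\lambda) = \big(\varepsilon_f(\lambda)[G] + \varepsilon_c(\lambda)[HG]\big)\,l$,
  so a red-shifted complex band drags the apparent UV maximum bathochromically
  as host is added.

Speciation follows mass action for $H + G \rightleftharpoons HG$ with
association constant $K$. The complex concentration is the physical root of
$K(G_t - c)(H_t - c) = c$, which we evaluate as
$c = 2 G_t H_t / \big(S + \sqrt{S^2 - 4 G_t H_t}\big)$, $S = G_t + H_t + 1/K$.
This form avoids the catastrophic cancellation of the textbook quadratic
formula at strong binding ($K \to \infty$, where $c \to \min(G_t, H_t)$) and
at weak binding alike; the test suite holds it to $10^{-10}$ relative
against a bisection oracle over $K \in [1, 10^8]$, $G_t, H_t \in
[10^{-6}, 10^{-2}]$ M.

Instrument ellipticity (mdeg) converts to differential absorbance through the
fixed constant $\theta[\mathrm{mdeg}] = 32982\,\Delta A$ (exposed as
`MDEG_PER_DELTA_ABS`), the standard CD convention; molar units then follow
Beer–Lambert with the total guest concentration. Conversions are exact
multiplications and round-trip to $10^{-12}$.

## Fitting the stability constant

Two fitters share the same model $y_i = \Delta\varepsilon_c\, c(G_t, H_i, K)\, l_i$:

* **Single wavelength** (`fit_k_single_wavelength`). Nonlinear least squares
  over $(\log_{10} K, \Delta\varepsilon_c)$, Levenberg–Marquardt,
  multi-started from $\log_{10} K \in \{1,\dots,5\}$ because the isotherm
  residual surface can be shallow for weak binding. No fitting protocol is
  canonical for ICD titrations, so the log-scale parameterisation was chosen:
  $K$ spans decades, is strictly positive, and its uncertainty is naturally
  multiplicative. Standard errors come from the Jacobian at the optimum
  (delta method for $K$ itself).
* **Global** (`fit_k_global`). Variable projection: for a trial $K$ the
  per-wavelength response $\Delta\varepsilon_c(\lambda)$ has a closed-form
  linear solution, leaving a smooth one-dimensional profiled residual in
  $\log_{10} K$, minimised on $[0, 6]$ by a coarse grid scan, golden-section
  refinement, and a two-step parabolic polish (golden section alone bottoms
  out near $\sqrt{\epsilon}$, which would spoil the consistency with the
  single-wavelength fitter on a one-point grid). The by-product is the full
  decomposed complex-only CD band.

Weighting is unweighted by default — no noise model is available for the
instrument — and a flat saturation curve is diagnosed, not rejected: when
the saturation fraction $c/G_t$ spans less than 0.2 across the series, the
fit is flagged `ill_conditioned`. This is the quantitative surrogate for the
qualitative observation that very weak ($\log K < 2$) and fully saturated
designs carry little information on $K$. Only 1:1 stoichiometry is modelled;
the quantitative claims this package supports are restricted to 1:1
complexes, and Job-plot or multi-site analyses are out of scope.

## Smoothing and band readout

`fft_lowpass` zeroes Fourier components above a fraction of the Nyquist
frequency of the uniform wavelength grid. The DC term is always kept (mean
preserved) and the mask is idempotent. The default `cutoff_fraction = 0.15`
retains band-scale structure (Gaussian bands of a few nm sigma on a 0.5 nm
grid) while removing point-to-point noise; no instrument filter parameters
were available to copy, so the default is justified by the property that it
strictly reduces RMSE against the clean band on seeded noisy input.
Non-uniform grids are an error by default — silent interpolation changes
the data — with explicit opt-in linear resampling to the median step.

`find_lambda_max` refines the grid maximum by the vertex of the parabola
through the maximum and its two neighbours, giving sub-grid-step precision
for smooth bands; ties break toward the lower wavelength, and a maximum on
the window edge is returned flagged rather than refined, since the parabola
would extrapolate.

## Cavity frame and sign prediction

The cavity frame is anchored on the glycosidic (O4) oxygen ring — the most
rigid, conformation-insensitive feature of the macrocycle — rather than on
an all-atom inertia tensor, which would drift with hydroxymethyl rotamers
and guest atoms. The origin is the O4 centroid; the axis is the smallest
principal direction of the centred O4 scatter (least-squares plane normal);
`planarity_rms` reports how well the ring supports the plane assumption.
The axis sign follows the narrow→wide convention, fixed by the secondary-rim
(O2/O3) centroid; without rim atoms the sign is arbitrary and flagged.

`classify_position` calls a chromophore centroid *inside* when it lies
within `half_height = 4.0` Å of the O4 plane and within
`radial_margin × ring_radius` of the axis (both boundaries closed). The
defaults reflect canonical β-cyclodextrin dimensions (cavity height ≈ 8 Å,
O4 ring radius ≈ 5 Å); the sign rules themselves are stated without
thresholds, so these are configurable.

`kodaka_harata_sign` encodes: inside + parallel → positive, inside +
perpendicular → negative, outside reverses both. "Parallel" and
"perpendicular" are separated at the magic angle
$\theta_m = \arccos(1/\sqrt{3}) = 54.7356^\circ$, where the orientation
factor $(3\cos^2\theta - 1)/2$ of coupled-oscillator theory changes sign;
within `magic_tol = 5°` of $\theta_m$ the prediction is *indeterminate*,
because near the node the sign is not robust to small orientation errors.
The dipole is treated as axis-sign-free, so angles fold to $[0, 90]^\circ$.
`predict_complex_sign` composes parse → frame → location → angle → rule and
requires the dipole components and the coordinates to share one Cartesian
frame; it never guesses a frame, since published dipole tables rarely state
one.

## What the generator emulates — and what it does not

`generate_titration` reproduces the statistical structure the analysis
assumes: constant guest concentration (fenoprofen-like default
$4\times10^{-4}$ M, 1 cm cell), a host ratio ladder (default 0, 1, 2, 5, 10,
20×; presets for the published three- and four-point designs), Gaussian
bands in wavelength, a ~3 nm bathochromic + hyperchromic UV shift on
complexation (≈10 nm for the nimesulide-like preset), a structured
complex-only CD envelope (two narrow Gaussians at 274.6 and 280.6 nm by
default), and additive Gaussian noise, independent per wavelength, with sd
expressed as a fraction of the peak clean signal. A seed is mandatory for
any noisy output and all draws are bit-reproducible.

Real spectra differ in ways the generator does not imitate: vibronic fine
structure beyond a sum of Gaussians, wavelength-dependent (heteroscedastic)
instrument noise, baseline drift and solvent blanks, and any deviation from
1:1 stoichiometry. Passing recovery tests therefore demonstrate that the
estimators are correct under the stated model, not that real titrations are
free of these systematics. `generate_toy_cyclodextrin` likewise reduces the
macrocycle to its oxygen scaffolding (7-fold O4 ring at 5 Å radius, rims at
±2 Å) — enough to exercise frame fitting and the sign rules, not a
conformational ensemble.

## Numerical sizes used in the tests

The shipped suite runs in well under a minute: titrations use 6 points × 161
wavelengths; the speciation oracle grid is 10×10×10; noisy-recovery studies
use 50–100 seeded replicates at 1–2% noise; geometric invariance uses 100
random rigid motions at $10^{-9}$ tolerance. These sizes were chosen so each
property is exercised far from its trivial regime while the whole suite
stays fast enough to run on every change.

## Known limitations

* 1:1 stoichiometry only; no Job plot, no 2:1/1:2 models.
* No vendor binary formats; spectra are plain-text header + two columns.
* No automated chromophore perception — the guest atom set is user-selected.
* The sign rule is qualitative by construction: it predicts a sign, not a
  rotational strength, and abstains near the magic angle.
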