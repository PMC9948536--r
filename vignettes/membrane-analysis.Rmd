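---
title: "Models and methods: monolayer thermodynamics, electrochemistry, spectroscopy and scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlayer)
```

`memlayer` implements the analysis chain used to characterise phospholipid
Langmuir monolayers and electrode-supported bilayers — the model system here
being mixed dimyristoyl-PE / dimyristoyl-PS films in their gel phase near
19 °C. Five measurement kinds are covered, each with its own reduction
model, and a synthetic-data module generates ground-truth-known inputs for
every stage so that the whole chain is testable without experimental files.
This vignette records the models, their assumptions, the tunable parameters,
and the design decisions taken where a choice was genuinely open.

## Isotherm mechanics and mixing thermodynamics

A compression isotherm is a series of (area per molecule $A$, surface
pressure $\Pi$) points at fixed composition $x_2$ and temperature $T$. Three
quantities are derived:

* **Compressibility modulus** $C_s^{-1} = -A\,(\partial\Pi/\partial A)$,
  evaluated pointwise; values of several hundred mN/m mark a solid film.
* **Excess area** $A^{exc} = A_{12} - (x_1 A_1 + x_2 A_2)$, the deviation of
  the mixed film from mole-fraction-weighted ideality at one pressure.
* **Excess Gibbs energy**
  $G^{exc} = N_A \int_0^{\Pi^\ast} A^{exc}(\Pi)\, d\Pi$, with the unit chain
  1 Å² · mN/m = 10⁻²³ J per molecule, and the **total** mixing energy
  $G^{mix} = RT(x_1\ln x_1 + x_2\ln x_2) + G^{exc}$ (with $0\ln 0 = 0$).

Numerical choices. Experimental isotherms are noisy, so the derivative in
$C_s^{-1}$ is taken on a Savitzky–Golay filtered series (defaults: 11-point
window, order 3, after resampling onto a uniform area grid); on noise-free
polynomial input this is exact. The excess-energy integral uses the
trapezoid rule on a common interpolated pressure grid (default 471 points
over [0, 47] mN/m; halving the grid moves smooth-input results by well under
0.1%). Below the lowest measured pressure the integrand is held constant —
an ideal-gas-limit treatment chosen because the behaviour of $A(\Pi)$ below
lift-off is unmeasured; integrating instead from the lift-off pressure is
possible by truncating the input isotherms, and for the near-ideal mixtures
studied here the difference is far below the experimental uncertainty.

Phase features are located on the smoothed derivative: the
liquid-expanded/liquid-condensed **plateau** is the first point on
compression where $|d\Pi/dA|$ falls below 2% of the maximum slope (the
tolerance is configurable; 2% separates coexistence flats from the gentle
liquid-expanded rise in practice), subject to a pressure floor of 5% of the
maximum pressure so the zero-pressure gas region is not mistaken for a
plateau. The condensed-to-solid **kink** is first bracketed at the
second-derivative extremum between plateau and solid branch, then refined as
the intersection of straight-line fits on either side — the smoothed value
*at* a corner is biased by half the filter window, while the two-line
intersection is exact for piecewise-linear input.

## Chronocoulometry

Potential-step transients (one per potential on a 0.05 V grid) are
trapezoid-integrated to relative charge densities; no exponential-tail
extrapolation is applied because the protocol holds each step long enough
for full decay — transients whose final current exceeds a floor are flagged
instead of corrected. Relative charges become absolute by anchoring the
bare-electrode curve to zero at its potential of zero charge (0.315 V for
Au(111) in NaF); film curves measured against the same desorption reference
receive the same additive offset. Cathodic current is negative throughout,
which orients the adsorbed-state window at roughly −10 to +15 μC/cm².

From the anchored curves: the slope $d\sigma/dE$ (central differences) is
the interfacial capacitance; adsorption-state boundaries are located at
isolated maxima of the interval slope exceeding 3× the median slope *and* a
robust noise floor (median + 5 MAD), with runs longer than two grid
intervals treated as capacitive branches rather than steps — a step is a
localized charge jump, a branch is not; and the bilayer **film pressure** is
the area between film and bare curves, $\Phi = \int (\sigma_{film} -
\sigma_{bare})\, dE$, with 1 μC·V/cm² = 10 mN/m. The integration window is a
required argument: the physically meaningful window depends on where both
states are well defined, which only the analyst knows.

## PM-IRRAS band analysis

Spectral regions are decomposed into pseudo-Voigt bands — a linear
Gaussian/Lorentzian mixture with per-peak centre, FWHM, height and mixing
fraction $\eta$ — six peaks in the C–H stretching region (methylene and
methyl symmetric/asymmetric stretches plus two Fermi resonances), three in
the C=O region. A true Voigt convolution was not used: the mixed line shape
is the standard choice for these condensed-phase bands and its closed-form
area, $\eta\,\frac{\pi}{2}hw + (1-\eta)\,\frac{hw}{2}\sqrt{\pi/\ln 2}$,
feeds the downstream ratios directly. The fit is Levenberg–Marquardt over
all centres (bounded within ±10 cm⁻¹ of the template), log-widths, heights
and a linear baseline fitted jointly; $\eta$ is held at its template value
by default because with six overlapping bands the mixing fractions are
weakly identified — freeing them is one flag away.

Two quantities follow from fitted areas. The **solvation fraction** of the
ester region is the ~1740 cm⁻¹ (non-hydrogen-bonded carbonyl) share of the
total C=O area; it is scale-invariant and monotone in the free-carbonyl
height. The **chain tilt** uses the metal-surface selection rule: only the
surface-normal field component is absorbed, so a band's integrated intensity
relative to a simulated isotropic (randomly oriented) reference obeys
$I/I_{iso} = 3\cos^2\theta$. The isotropic reference is an *input* here
(per-band reference areas or a reference spectrum): computing it requires a
transfer-matrix optical model of the cell with measured optical constants,
which is upstream of this package. The methylene symmetric and asymmetric
dipole angles then give the chain tilt through orthogonality,
$\cos^2\theta_s + \cos^2\theta_{as} + \cos^2\theta_{chain} = 1$; the
$\cos^2$ sum is clamped when it exceeds 1 by at most 0.02 (intensity noise)
and is an error beyond that. The methyl and Fermi-resonance bands are fit
components only and never enter the ratios.

## GIXD indexing

In-plane Bragg peaks in integrated $I(q_{xy})$ profiles are fitted as
pseudo-Voigt lines over a linear background, initialised at the strongest
separated local maxima; featureless profiles return zero peaks and fitted
amplitudes below 3× the residual scale carry a weak-feature flag. Bragg-rod
maxima are Gaussian-plus-constant fits in $q_z$, clamped at zero.

A single peak with its rod maximum at $q_z = 0$ is an untilted hexagonal
chain lattice ({1 0}, {0 1}, {1 1̄} spacings degenerate): $d = 2\pi/q$,
$a = 2d/\sqrt{3}$, area per chain $\frac{\sqrt{3}}{2}a^2$. Three peaks (a
degenerate pair may be passed twice) are assigned to {1 0}, {0 1}, {1 1̄};
the law of cosines on the reciprocal triangle gives the reciprocal cell, and
the rod relation $q_z = |\mathbf{G}\cdot\hat{u}|\tan t$ — powder averaging
makes rod signs unobservable, so the sign combinations are enumerated and
the best least-squares tilt vector kept (residuals beyond a tolerance are an
indexing failure). Among valid label assignments the smallest cell area wins
(lowest-index convention), and the final basis is Lagrange-reduced to the
canonical shortest-vector cell with obtuse γ, so equivalent bases of the
same lattice always report identically. Chains per lipid is fixed at 2
(dimyristoyl chemistry); area per molecule is twice the chain cell area, and
the chain cross-section is the projected area times $\cos t$.

## Slab-model reflectometry

Specular reflectivity of an air / tails / solvated-headgroup / subphase
stack is computed two independent ways — an Abeles characteristic-matrix
product and a bottom-up Parratt recursion — both with Névot–Croce Gaussian
roughness factors $\exp(-2k_nk_{n+1}\sigma^2)$ on the interface Fresnel
coefficients. The two routes are algebraically equivalent and the test suite
holds them to within 10⁻¹⁰ relative on random stacks; error-function
microslabbing was not used because at the roughness-to-thickness ratios of
these monolayers (≈3 Å vs ≥7.5 Å) the Névot–Croce factor is the standard
and adequate treatment. Resolution smearing is a Gaussian convolution in
$q$ with $\sigma = (dq/q)\,q/2.355$, by 17-point fixed quadrature over
±3.5σ, matching the constant-7% FWHM resolution of time-of-flight
reflectometers.

The two-slab monolayer model ties its parameters together physically: the
tail slab contains the two (perdeuterated) chains, so the area per molecule
is $A = V_{tail}/t_{tail}$; the headgroup slab includes the ester carbonyls,
and because the molecular area must be equal in both slabs its solvated
volume is $V_{solv} = A\,t_{head}$, part dry headgroup and part water. The
head-slab SLD per contrast is $(b_{head} + n_w b_{water})/V_{solv}$ with
$n_w = \phi V_{solv}/V_w$. Co-fitting shares $(t_{tail}, t_{head},
\sigma, \phi)$ across contrasts while the solvent terms switch with the
subphase (D₂O vs air-contrast-matched water, ACMW). Modes: weighted
Levenberg–Marquardt least squares, or a seeded affine-invariant
(stretch-move) ensemble sampler over the same likelihood (defaults 32
walkers, 30% burn-in) for 95% intervals.

The **solvation calculation** inverts the head-slab composition: with the
fitted D₂O-contrast head SLD, $n_w = (\rho_{obs}V_{solv} - b_{head}) /
b_{water}$ and $V_{dry} = V_{solv} - n_w V_w$; negative water counts or
non-positive dry volumes are an unphysical-solution error, which is the
working criterion for rejecting an assumed H/D-exchange count. Labile
headgroup hydrogens exchanged in D₂O add $b(D)-b(H) = 10.41$ fm each to
$b_{head}$; X-rays see no exchange, so running the identical algebra with
electron-count scattering lengths ($e \times r_e$) on XRR fits provides the
cross-check — consistent $n_w$ from both routes bounds the exchange level.
Molecular volumes are always explicit inputs (defaults only for water:
29.96/30.13 Å³ near 20 °C) because literature headgroup volumes conflict;
the shipped PE/PS fragment materials (tails 722 Å³, dry head 252 Å³,
nominal formulas) are plain fields meant to be overridden. All SLDs are
carried in 10⁻⁶ Å⁻² and scattering lengths in fm to keep exponents out of
user code; mixture headgroup scattering lengths are mole-fraction-weighted.

## What the generators emulate — and what they do not

Each stage has a generator that serializes its ground truth beside the
data, is bit-reproducible for a given seed, and refuses to emit stochastic
output without one:

* `gen_isotherm()`: piecewise-smooth compression curves with a prescribed
  plateau pressure, kink pressure, solid-branch slope and limiting area
  (defaults 20 and 35 mN/m, 40 Å², chosen to resemble gel-phase
  dimyristoyl lipids); `gen_isotherm_family()` builds a binary composition
  series with a prescribed excess-area function, so mixing energies are
  known in closed form.
* `gen_transients()`: exponential-decay current transients whose integrals
  equal a prescribed σ(E) exactly (amplitudes are truncation-corrected),
  on the 0.05 V protocol grid with steps at −0.40 and −0.80 V by default.
* `gen_ir_spectrum()`: six C–H or three C=O pseudo-Voigt bands whose
  methylene areas encode a prescribed tilt via the dipole relation (the
  tilt is split equally between the two CH₂ dipoles, i.e. a 45° chain
  twist — real chains vary in twist, which the analysis never needs to
  know) or whose 1740 cm⁻¹ share equals a prescribed solvation fraction.
* `gen_gixd()`: pseudo-Voigt peaks at the exact reciprocal positions of a
  truth lattice with rods placed by the tilt relation; degenerate
  reflections merge with summed intensity.
* `gen_reflectivity()`: paired D₂O/ACMW curves from one structural truth,
  7% smearing, and seeded noise either flat (1%) or growing with $q$
  (counting-statistics-like, the default, because fit weighting should be
  exercised against realistic error bars). The head solvent fraction
  follows from the geometry ($\phi = 1 - V_{head}/A t_{head}$), spanning
  roughly 0.1–0.5 over the tail 14–18 Å, head 7–10 Å regime.

What passing the round trips does **not** show about real data: the
generators draw from the same line-shape and slab families the fitters
assume, so they validate the inverse machinery (identifiability, noise
propagation, convergence), not model adequacy. Real spectra have curved
baselines and band asymmetry; real reflectivity has background, imperfect
deuteration and off-specular contamination; real isotherms have hysteresis
and leakage drift. None of those imperfections is emulated.

## Problem sizes and limitations

The shipped studies use desk-scale sizes: 90-point reflectivity curves per
contrast and 20 seeded dataset pairs for the recovery study; 400-point
isotherms; 0.5 cm⁻¹ spectral grids; 600-point diffraction profiles. These
sizes put every parameter comfortably above the noise floor while keeping
the full suite and drivers in tens of seconds; they are the package's
reference conditions, stated here so deviations are deliberate.

Known limitations: no instrument reduction (detector images, PEM
demodulation, splicing) — the package starts from reduced profiles; no
transfer-matrix IR optics (the isotropic reference is an input); no
Bragg-rod form-factor modelling, so coherence lengths and rod widths are
not interpreted; the reflectivity model is absorption-free and specular
only; no equation-of-state fitting of the expanded phase; and the
electrochemistry treats the electrode as a capacitor sequence — no kinetic
analysis of transient shapes.
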