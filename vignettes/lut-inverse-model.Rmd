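---
title: "Lookup-table inverse modeling for sub-diffuse reflectance spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lookup-table inverse modeling for sub-diffuse reflectance spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrslut)
```

## The problem

Fiber-probe reflectance spectroscopy at source-detector separations (SDS)
shorter than one reduced mean free path — *sub-diffuse* reflectance
spectroscopy, sDRS — interrogates a few hundred micrometres of superficial
tissue, the depths where oral epithelial dysplasia develops. At these
separations the diffusion approximation is not valid, so optical properties
cannot be recovered by inverting an analytic transport model. The standard
workaround is empirical: measure calibration phantoms of known reduced
scattering $\mu_s'(\lambda)$ and absorption $\mu_a(\lambda)$, interpolate
the measured absolute reflectance onto a regular $(\mu_s', \mu_a)$ grid — a
lookup table (LUT) per SDS — and fit unknown spectra by searching the LUT
under a low-dimensional tissue model.

This package implements that pipeline end to end and, because no physical
probe is attached, pairs it with a synthetic instrument surrogate so the
full calibration-validation study runs at desk scale. The surrogate is a
*documented stand-in*, not a photon-transport model; what the package
validates is the pipeline (recipes, calibration, LUT construction,
inversion, depth estimation), not sub-diffuse physics.

## The tissue model

Over the 500–750 nm fit window the model has four parameters. Scattering
follows a power law anchored at $\lambda_0 = 630$ nm,

$$\mu_s'(\lambda) = \mu_s'(\lambda_0)\,(\lambda/\lambda_0)^{-B},$$

with scattering exponent $B$ related to the size of the tissue's dominant
scatterers. Absorption is hemoglobin alone,

$$\mu_a(\lambda) = \ln(10)\,\frac{[\mathrm{Hb}]}{MW}\,
 \bigl[\alpha\,\varepsilon_{\mathrm{HbO_2}}(\lambda) +
 (1-\alpha)\,\varepsilon_{\mathrm{Hb}}(\lambda)\bigr],$$

with concentration $[\mathrm{Hb}]$ in mg/mL (numerically g/L, so dividing
by the gram molecular weight $MW = 64{,}500$ g/mol gives molarity
directly), saturation $\alpha \in [0,1]$, and base-10 molar extinction
$\varepsilon$ in cm$^{-1}$M$^{-1}$. Vessel-packaging corrections are out of
scope: they matter below 450 nm and the fit window starts at 500 nm.

The packaged extinction table
(`inst/extdata/hemoglobin_extinction_synthetic.csv`) is *synthetic*: a
smooth parametric reconstruction (anchor points splined in log space) of
the canonical features of adult hemoglobin — Soret bands near 414/430 nm,
oxy Q-band doublet at 542/577 nm, deoxy single Q band at 555 nm,
isosbestic crossings near 500/522/546/570/588/796 nm, and a deoxy/oxy
ratio near 8 at 630 nm. It is not a measured compilation; since the same
table drives both the spectrum generator and the fit, every round-trip
result in this package is internally consistent, but absolute $\mu_a$
values should not be compared against measured hemoglobin data.

## Calibration phantom recipes

Calibration phantoms are aqueous suspensions of 1.0 µm polystyrene
microspheres. Their $\mu_s'(\lambda)$ comes from Lorenz–Mie theory
(Wiscombe truncation, downward recurrence for the logarithmic derivative;
an independently coded Bessel-function series serves as the test oracle)
with Cauchy-type dispersion models for polystyrene and water. The sphere
population carries a 3% diameter coefficient of variation, typical of
manufactured lots; this also smooths monodisperse Mie ripple so
$\mu_s'(\lambda)$ decreases strictly over 450–750 nm.

Six scattering-only phantoms are anchored so that $\mu_s'(750\,\mathrm{nm})$
equals 3.0, 4.4, 6.4, 9.2, 13.2 and 19.5 cm$^{-1}$ (volume fractions solved
by bisection; scattering is exactly linear in volume fraction in the dilute
regime). A design note: Mie theory for 1.0 µm polystyrene gives a
450/750 nm band ratio of about 1.31, so each phantom's band is narrower
than the commonly quoted $\sim$1.6 ratio for this recipe family; the six
bands therefore do not satisfy the strict 90% band-overlap continuity rule
(`check_overlap()` reports signed margins rather than asserting
continuity), and the LUT instead relies on interpolation across the
inter-band gaps.

Six further phantoms add a synthetic dye — two Gaussian absorption bands at
520 and 630 nm, an arbitrary smooth spectrum standing in for the paper
dye's unpublished extinction — with scattering anchors
$\{4.4, 6.4, 9.2, 13.2, 19.8, 20.5\}$ cm$^{-1}$ and dye peaks
$\{16, 22, 28, 38, 47, 3\}$ cm$^{-1}$. The pairing is deliberate: the two
high-scattering phantoms split into a high-dye and a low-dye member so the
pooled phantom trajectories reach all four corners of the LUT target
rectangle ($\mu_s' \in [5, 26]$, $\mu_a \in [0, 10]$ cm$^{-1}$); measured
hull coverage exceeds 99%. Validation phantoms (3 scattering levels
$\times$ 3 hemoglobin concentrations $\{1.0, 2.6, 5.0\}$ mg/mL, fully
oxygenated by default) stay inside that rectangle at every wavelength of
the fit window while jointly spanning it.

## The instrument surrogate

`surrogate_reflectance()` is a Farrell-type extrapolated-boundary dipole
with two deliberate modifications that make it *monotone by construction*
over the LUT range — strictly increasing in $\mu_s'$, strictly decreasing
in $\mu_a$, at both SDS: the transport depth $z_0 = 1/\mu_s'$ ignores
absorption, and the effective attenuation
$\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_{s0})}$ uses a fixed
$\mu_{s0} = 15$ cm$^{-1}$ instead of the true $\mu_s'$. The unmodified
Farrell form is non-monotone at these short separations, which would break
the LUT pipeline's basic premise; the surrogate trades physical fidelity
for the qualitative structure the pipeline needs. Internal reflection uses
a 1.4/1.0 index mismatch (tissue-like), and a fixed collection constant
(0.01) sets the absolute scale.

Detected signal accrues over depth as a stretched saturating profile
$F(z) = 1 - \exp[-(z/z_s)^{1.5}]$ with scale
$z_s = c_1\,\mathrm{SDS}^{c_2} / (1 + c_3 \mu_{att})$,
$\mu_{att} = \sqrt{3(\mu_a + 0.05\mu_s')(\mu_a + \mu_s')}$. The constants
$c_1 = 80.126$, $c_2 = 0.37257$, $c_3 = 0.039417$ were calibrated once,
analytically, so the median depth $D_{50} = z_s (\ln 2)^{2/3}$ spans
roughly 240–530 µm at the 374 µm SDS and 300–680 µm at 730 µm across the
LUT target range, deeper for the longer separation and shallower with
increasing absorption or scattering. They are package constants, not free
parameters.

The raw-signal model is `counts = gain × R × lamp(λ) + dark + noise`
(3000 K Planck-like lamp shape, gain $10^6$, dark 100 counts), with 1%
multiplicative noise and 1 count additive dark noise per frame and five
frames averaged per measurement. Calibration against a paired 20% diffuse
standard frame cancels the lamp exactly (a property test injects random
lamp shapes). Layered samples are reduced to depth-weighted effective
properties using $F$ evaluated with the top layer's optics; translation
curves are $R_{semi} \cdot F(d)$ on a 0–2 mm, 50 µm grid with a
specular-free contact point.

What the surrogate does *not* emulate: real sub-diffuse phase-function
sensitivity, multi-layer internal reflections, wavelength-correlated noise,
probe-pressure artifacts, and a reflectance ratio between channels matching
the real instrument's. Passing round trips therefore demonstrate the
pipeline's correctness and numerical health, not accuracy on real tissue.

## LUT construction

All twelve phantoms contribute pooled per-wavelength points
$(\mu_s'(\lambda), \mu_a(\lambda), R(\lambda))$ (about 1,800 points per
SDS at 2 nm decimation). The surface is reconstructed on the regular grid
(0.02 cm$^{-1}$ step, 1051 × 501 nodes) in log-reflectance space in two
stages: a global degree-8 bivariate polynomial least-squares fit captures
the smooth surface, and the fit residuals are spread by Delaunay
triangulation with linear interpolation, keeping the reconstruction exact
at every data point. Plain triangulation alone leaves 5–7% RMS error in
the gaps between phantom trajectories (log-reflectance is strongly curved
there); the two-stage build measures 0.5–0.7% RMS against the forward
model on a 50 × 50 probe grid. Nodes outside the data hull (< 0.1% of the
grid) are filled by nearest-neighbour propagation and flagged in the
provenance; a build whose hull covers less than 95% of the target
rectangle fails with a gap report. Sampling-depth LUTs use the same
machinery on 50%-crossing depth estimates from the six absorbing phantoms.
Tables persist to a single-file text format (JSON header with schema
version and checksum, CSV payload) chosen over binary containers for
portability.

## Inversion

`fit_spectrum()` minimizes the sum of squared *relative* residuals
$(R_{obs} - R_{model})/R_{obs}$ with Levenberg–Marquardt under box bounds
($\mu_s'(630) \in [5, 26]$, $B \in [0, 4]$,
$[\mathrm{Hb}] \in [0, 20]$ mg/mL, $\alpha \in [0, 1]$). Relative
weighting is the maximum-likelihood choice under multiplicative noise and
keeps the dim hemoglobin Q-band region informative; with absolute
residuals the weakly scattering-sensitive 730 µm channel occasionally
falls into a spurious boundary minimum ($\mu_s' \to 26$, $B \to 0$).
Sixteen starts (a 4 × 4 grid over $\mu_s'(630)$ and $B$, including a
low-$B$ start, with a central chromophore start of 2 mg/mL at 80%
saturation) guard against local minima; the best final objective wins,
ties broken by parameter norm. Model trajectories leaving the LUT range
are clipped with a quadratic penalty; a solution whose mean excursion
exceeds 0.01 cm$^{-1}$ is flagged not converged, while microscopic
edge-touching (a model dipping 0.04 cm$^{-1}$ below the $\mu_s' = 5$ axis
at 750 nm) is tolerated.

Residual noiseless round-trip errors have two floors: LUT interpolation
(~0.5%) and the power-law approximation to the microspheres' Mie spectrum
(0.7% mean over the window). The 374 µm channel recovers both properties
within 1% noiselessly; the 730 µm channel's weaker scattering sensitivity
at high $\mu_s'$ leaves it near 1.4%, so "interpolation-only" accuracy is
not fully attainable there.

## Study pipelines and problem sizes

Four scripted studies reproduce the validation suite; all are pure
functions of `(config, seed)`:

* `run_phantom_validation()` — 12-phantom calibration, 9-phantom
  hemoglobin validation, 18 fits, percent-error tables. Default problem
  size: 2 nm spectral decimation (151 wavelengths), full 0.02 cm$^{-1}$
  LUT grid; about half a minute on one core. Typical results: mean
  $\mu_s'$/$\mu_a$ errors ≈ 1.8%/3.0% at 1% noise and ≈ 1.5%/2.3% at
  0.5% noise, against the 10% field benchmark.
* `run_depth_validation()` — translation curves (41 distances) for the six
  absorbing calibration phantoms build the depth LUTs; the nine validation
  phantoms' estimated depths check them (≈ 1% mean error). Wavelengths
  whose plateau cannot settle because extreme dye absorption starves the
  detector are dropped with QC flags rather than aborting the batch.
* `run_dysplasia_progression()` — three two-layer phantom stages (150 µm
  sublayers; healthy 7 cm$^{-1}$, dysplastic 14 cm$^{-1}$ at 630 nm over a
  1 cm base) at both SDS, ten noisy repeats each, fitted volume-averaged
  $\mu_s'(630)$, percent increases and paired t-tests at $\alpha = 0.01$
  comparing channels. The homogeneous stage recovers exactly 7 cm$^{-1}$
  noiselessly; increases are strictly larger at the shallow SDS.
* `run_cohort_fit()` — a 13-subject synthetic cohort whose generating
  distributions place the shallow/deep channel means at the package's
  reference values ($B$ 0.80 vs 0.48, $[\mathrm{Hb}]$ 2.39 vs
  2.91 mg/mL, SaO$_2$ 94.1% vs 91.7%) with a shared subject effect;
  recovery, channel-offset direction, and paired t-tests (saturation
  non-significant by design) are reported.

The test suite runs the same pipelines at reduced sizes (coarser LUT steps,
4–16 nm decimation, fewer repeats); the acceptance script runs them at the
default sizes above.

## Numerical choices and degenerate inputs

Bisection for volume fractions exploits exact linearity and is iterated to
machine tolerance. The 50% crossing uses linear interpolation between the
50 µm translation steps — higher order is unjustified at that sampling —
with the plateau defined as the mean of the last three distances and a 1%
concordance gate; a curve still rising there is an error (or an `NA` with
a QC flag in batch mode). Depth estimates are invariant to overall curve
scaling. Bilinear LUT lookup is exact at nodes and raises a range error
naming the violated axis. Calibration rejects non-positive
standard-minus-background denominators and flags wavelengths within five
additive-noise floors of zero. Degenerate phantom geometries (no
semi-infinite base, multiple infinite layers, unordered translation
distances) are structural errors.

## Known limitations

The surrogate's reflectance-ratio structure between channels does not
match the real probe's (its empirical 730/374 reflectance ratio statistics
are not reproduced; the depth-ratio direction is). The synthetic dye and
hemoglobin spectra are stand-ins, so absolute recovered chromophore values
are only internally meaningful. Monodisperse-lot effects, vendor file
formats, wavelength-axis recalibration, and SDS channels beyond the two
presented (1,051 and 1,323 µm exist only as configuration) are out of
scope. Paired t-tests follow the two-channel design; more channels would
need a different comparison structure.
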