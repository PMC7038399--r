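---
title: "Optical water type guided retrieval of lake water quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical water type guided retrieval of lake water quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeowt)
```

## The problem

Boreal lakes are optically complex: chlorophyll-a (Chl-a), total suspended
matter (TSM) and colored dissolved organic matter (CDOM) vary independently,
so no single band-ratio algorithm retrieves water quality well across all
waters. The approach implemented here classifies each reflectance spectrum
into one of five optical water types (OWTs) first — Clear, Moderate, Turbid,
Very Turbid (bloom-dominated), Brown (CDOM-dominated) — and then applies the
retrieval algorithm calibrated for that class. The package covers the whole
chain: spectral resampling to Sentinel-2 MSI and Sentinel-3 OLCI bands, OWT
classification, per-OWT retrieval of Chl-a (mg m⁻³), TSM (mg L⁻¹), CDOM
absorption at 400 nm (m⁻¹) and Secchi depth (m), and match-up validation
statistics. A synthetic bio-optical generator supplies labelled test data,
since the underlying field campaign data are not public.

Throughout, *reflectance* means dimensionless remote-sensing reflectance
(water radiance over white-panel radiance); no π scaling is applied
anywhere. Negative reflectances — which atmospheric correction can produce —
are retained and flagged, never clipped, and flow into the retrieval
formulas as-is.

## Band systems and spectral resampling

Hyperspectral spectra are resampled to sensor bands by a spectral response
function (SRF) weighted mean: the SRF–reflectance product is integrated by
trapezoid rule on the union of the SRF and spectrum grids, with linear
interpolation between samples, and divided by the SRF integral. This makes
the operation exact for constant spectra and linear in the spectrum, both of
which are property-tested. Measured SRFs can be supplied as (band,
wavelength, weight) tables; when only band centers and widths are known,
Gaussian SRFs are synthesized from center and FWHM. The OLCI bands at
673.75, 681.25 and 709.5 nm are keyed by integer center (`R674`, `R681`,
`R709`).

Observation tables use the column dialect `<SOURCE>_R<center>` for band
reflectances and `<SOURCE>_<field>` for processor product fields
(`conc_tsm`, `Kd_489`, ...), with sources `TOA`, `C2RCC`, `C2X` (C2X exists
for MSI only; requesting it for OLCI is an error).

## OWT classification

A spectrum is assigned to the class whose reference spectrum it most
resembles under the mean of two shape measures:

* **Spectral correlation similarity (SCS)**: `(ρ + 1) / 2` with ρ the
  Pearson correlation of the band vectors — 1 for identical shape, 0 for
  mirrored shape.
* **Modified spectral angle similarity (MSAS)**: `1 − (2/π)·arccos(cos θ)`
  with θ the angle between the band vectors — 1 for parallel vectors, 0 at
  a right angle. When negatives occur, both vectors are shifted by their
  common minimum so the angle stays meaningful.

These closed forms are this package's definitions: the originating
classification method names the two measures without printing formulas, so
bounded, scale-invariant versions consistent with those names were adopted
and isolated behind two small functions that can be swapped for other
definitions. The combination rule (arithmetic mean) and the unclassified
threshold (combined score < 0.8, configurable) are likewise package choices:
the mean preserves bounds and symmetry, and a cutoff is needed because
unclassifiable pixels demonstrably occur in practice. Exact ties are broken
by the fixed class order Clear → Brown and recorded. Constant, zero, or
incomplete spectra are degenerate: they score 0 and come back
`Unclassified` with a flag rather than erroring.

Classification uses all visible–NIR bands up to 865 nm of each sensor by
default. The shipped reference library is built from the synthetic
archetypes below and is a documented stand-in; a published boreal reference
set can be loaded from CSV with `read_reference_library()`.

Misclassifications are graded by distance: the pairs Clear–Turbid,
Clear–Very Turbid, Clear–Brown and Turbid–Brown count as *large*
differences, all other unequal pairs as *little*.

## The retrieval registry

Every best-per-OWT algorithm is one declarative entry: (sensor, product,
OWT) → reflectance source, predictor expression, response form,
coefficients, predictor domain. The builtin registry has all
2 × 4 × 5 = 40 entries; a JSON config can override any of them. Predictors
are plain arithmetic over band tokens (`R705/R665`,
`R709 - (R665 + R754)/2`, `R620*R681/R510`), an external processor field,
or the `kd490` operator. Response forms are linear, quadratic, power and
exponential.

Three encoding decisions deserve note:

* The CDOM entries published against a 550 nm band are encoded on the
  560 nm band — neither sensor carries 550 nm, and 560 nm is the nearest
  green band on both; the entry carries a provenance note.
* `R779 − R754 + R865/2` binds as `(R779 − R754) + R865/2`, i.e. plain
  left-to-right arithmetic, consistent with the analogous MSI expression
  `R783 − R740 + R865/2`; a user registry entry can encode the alternative
  reading if wanted.
* Quadratic responses are non-monotonic, so each such entry carries a
  predictor domain spanning a plausible calibration range; outside it the
  output is missing with a diagnostic rather than extrapolated.

The Secchi chain: the per-OWT SD formulas consume a diffuse-attenuation
predictor — either a processor `Kd_489` field or the `kd490` operator
computed from R490, R560 and the red-edge band (705 nm MSI / 709.5 nm
OLCI). The `kd490` internals are a configurable log-linear band-ratio
model, `Kd490 = 10^(a0 + a1·log10(R490/R560) + a2·log10(Rred/R560))`, with
documented placeholder defaults (a0 = 0.05, a1 = −1.2, a2 = 1.0) chosen to
give plausible boreal magnitudes and monotone increase in the red band; the
published calibration of this operator is not reproduced here and users with
access to it should substitute their coefficients. The generic transforms
`KdPAR = 0.4349·Kd490 + 0.3291` and `SD = 1.6941·KdPAR^−0.677` are exposed
as `kd_par()` and `secchi_from_kdpar()` (the printed exponent uses a comma
decimal; it is read as −0.677).

Missing inputs always propagate to missing outputs — never a silent zero —
and each retrieved value records which source and formula produced it.

## Validation statistics

`r_squared()` implements `1 − SSres/SStot` literally, so worse-than-mean
predictions go negative (no clamping); `rmse()` is the root mean squared
error in product units. Match-ups pair in-situ samples and satellite
observations of the same station within ±1 day at date granularity (time of
day is not used); each qualifying pair contributes independently, and a
station can yield several match-ups. MSI rows are expected to carry 3×3
pixel window means computed upstream, OLCI single-pixel values; the window
used is recorded per match-up. Summaries report n, R² and RMSE per group
and pooled over all pairs (pooled-pairs, not group-averaged) for three
grouping schemes: by lake, by binned in-situ value (default cutpoints at
the terciles, configurable), and by derived OWT. Groups with fewer than two
pairs are flagged, not merged.

## The synthetic generator

The generator emulates the *study conditions*, not the actual campaign
spectra. A deliberately simple semi-analytical forward model produces
reflectance as `R(λ) = f·bb/(a + bb)` with absorption summed from pure
water (tabulated 380–900 nm), chlorophyll (Gaussian peaks near 440 and
675 nm plus a green accessory-pigment shoulder), CDOM
(`exp(−S(λ − 400))`, S = 0.018 nm⁻¹) and non-algal particles, and
backscatter from water plus TSM-proportional particles. Archetype centers
follow the four study-lake regimes: Clear (Chl-a 5 mg m⁻³, TSM
1.7 mg L⁻¹, CDOM 1.6 m⁻¹ — an oligotrophic clear lake), Moderate
(15/8/3.5), Turbid (20/30/3.5, TSM-dominant), Very Turbid (110/15/3,
bloom-dominant with the red-edge reflectance peak this implies), Brown
(10/5/8, CDOM ≥ 5 m⁻¹, dark). Draws are log-normal around the centers
(distributions are not specified by the source material; log-normality is
an assumption) with class floors enforced (Very Turbid Chl-a ≥ 30, Brown
CDOM ≥ 5). Sources are derived from the water-leaving spectrum by simple
transforms: C2RCC × 0.85 (systematic underestimation), C2X × 0.95, TOA
plus a Rayleigh-like path term `0.09·(450/λ)^3.5`.

Match-up tables and scenes are generated differently, on purpose:

* **Match-ups** guarantee product consistency by construction: for each
  record and product, a predictor value is sampled on the registry entry's
  monotone branch, the in-situ truth is the printed formula applied to it,
  and the band values are solved (per sensor and OWT, in an order where
  later solves never disturb earlier ones) so the predictor evaluates to
  exactly that value. At noise 0 retrieval is therefore exact — R² = 1,
  RMSE = 0 — which is the test anchor; relative Gaussian noise on the
  in-situ products then degrades it controllably. Sampling the predictor
  and computing the truth forward (rather than drawing the product and
  inverting the response) avoids the non-invertible regions of the
  quadratic forms; the one predictor shared by two products (the OLCI
  Turbid TSM/CDOM pair) is sampled once and drives both truths.
* **Scenes** run the forward optics per pixel (with log-normal parameter
  jitter) so the classifier sees realistic spectral shapes; truth labels
  are stored alongside. Identical seeds give bit-identical output; every
  stochastic operation takes its seed explicitly and restores the global
  RNG state.

What passing tests therefore show — and do not show: the closed-loop
results demonstrate that the formula encodings, the solver and the
validation statistics are mutually consistent and that the classifier
separates the *synthetic* archetypes (self-similarity exceeds
cross-similarity with margin > 0.02 on both sensors' band sets). They say
nothing about accuracy on real lakes, which depends on atmospheric
correction quality and on reference spectra this package does not ship;
the headline validation figures of the originating study are not
reproducible without its unreleased match-up data and are deliberately not
targeted.

## Numerical choices and problem sizes

Resampling uses trapezoid integration on union grids (constant-preserving
to 10⁻¹², linear to 10⁻¹⁰ in tests). Similarity scores are clamped only at
the arccos argument (±1) to absorb rounding. Coefficient-recovery tests
regress pipeline output on 50-point noise-free predictor grids and demand
relative agreement to 10⁻⁶ (log-space regression for power/exponential
forms). The test suite uses 16×16 scenes, 30–120 match-ups for closed-loop
checks, and 500 match-ups for the noise-calibration check, all seeded;
these sizes keep the suite fast while leaving the Monte-Carlo checks
well-determined.

## Limitations

No atmospheric-correction or pixel-identification internals are modelled —
processor outputs are consumed as input columns. No geolocation,
reprojection or image IO beyond gridded arrays; no in-water vegetation
masking; no radiative-transfer fidelity in the forward model; no re-fitting
of algorithm coefficients to new data. The shipped reference spectra and
the Kd490 coefficients are synthetic/placeholder components and are
documented as such at their definitions.
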