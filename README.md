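# lakeowt

Optical water type (OWT) guided retrieval of lake water quality from
Sentinel-2 MSI and Sentinel-3 OLCI reflectance.

Boreal lakes are optically complex: chlorophyll-a, suspended matter and
dissolved organic matter vary independently, so a single retrieval
algorithm fails across lake types. `lakeowt` implements the two-step
approach used in modern lake remote sensing: classify each reflectance
spectrum into one of five optical water types — Clear, Moderate, Turbid,
Very Turbid (bloom), Brown (CDOM-rich) — and then apply the retrieval
model calibrated for that class. The package is aimed at limnologists and
remote-sensing practitioners who need a tested, scriptable version of this
pipeline, plus a synthetic bio-optical generator for end-to-end testing.

## What it computes

* **Band resampling** — hyperspectral remote-sensing reflectance R(λ) to
  MSI/OLCI bands via spectral response functions (SRF-weighted trapezoid
  means; Gaussian SRFs synthesized from center/FWHM when tables are
  unavailable).
* **OWT classification** — label = argmax over classes of the combined
  shape similarity ½(SCS + MSAS), where SCS = (ρ + 1)/2 (rescaled Pearson
  correlation) and MSAS = 1 − (2/π)·arccos(⟨x,r⟩/‖x‖‖r‖); spectra below a
  combined-score threshold (default 0.8) come back `Unclassified`.
* **Per-OWT retrieval** — a declarative 40-entry registry
  (2 sensors × 4 products × 5 OWTs) of band-ratio and processor-product
  models, e.g. Chl-a = 293.5·(R705/R665) − 263.4 for Brown-water MSI
  scenes, evaluated per observation or per pixel. Secchi depth runs
  through the attenuation chain KdPAR = 0.4349·Kd490 + 0.3291,
  SD = 1.6941·KdPAR^−0.677.
* **Validation** — ±1-day satellite/in-situ match-up construction and
  R² = 1 − SSres/SStot, RMSE = √(Σ(yᵢ−ŷᵢ)²/n), OWT accuracy and
  error-magnitude distributions, grouped by lake, by in-situ bins, or by
  OWT.
* **Synthetic data** — a semi-analytical forward model
  R(λ) = f·b_b/(a + b_b) generating labelled archetype spectra, scenes
  and match-up tables with known ground truth.

## Worked example

```r
library(lakeowt)

# classify a CDOM-rich synthetic spectrum against the shipped references
lib  <- default_reference_library("MSI")
arch <- generate_archetype("Brown", seed = 7)
x    <- resample_to_bands(arch$spectrum, band_set("MSI"))
classify(x, lib)
#> <owt_similarity> label Brown (combined 0.977, margin 0.014)
#>         owt       scs      msas  combined
#>       Clear 0.9053126 0.7517259 0.8285193
#>    Moderate 0.9859308 0.9209390 0.9534349
#>      Turbid 0.9960603 0.9293906 0.9627255
#>  VeryTurbid 0.9056684 0.7893106 0.8474895
#>       Brown 0.9965047 0.9568936 0.9766992

# OWT-guided retrieval on one observation row (column dialect SOURCE_Rband)
retrieve(data.frame(TOA_R705 = 0.02, TOA_R665 = 0.01), "Brown", "MSI")
#>     chl tsm cdom400 sd
#> 1 323.6  NA      NA NA
```

The red/NIR ratio is 2.0, and the Brown-water chlorophyll model
`y = 293.5x - 263.4 on TOA R705/R665` gives 323.6 mg m⁻³; the other
products are missing because this row carries no C2RCC/C2X columns —
missing inputs always propagate, never silently zero-fill.

```r
# closed loop: synthetic match-ups with 10% noise, validated by OWT
gm <- generate_matchups(60, "MSI", noise_sd = 0.1, seed = 42)
mu <- retrieve_table(build_matchups(gm$insitu, gm$satellite, "MSI"),
                     "owt", "MSI")
summarize_matchups(mu, "chl", "by_owt")
#>       group  n        r2      rmse flagged
#>       Brown 10 0.9711670 3.9387753   FALSE
#>       Clear 13 0.9800929 0.4245072   FALSE
#>    Moderate 14 0.9210653 3.0662383   FALSE
#>      Turbid 16 0.8661098 4.6367116   FALSE
#>  VeryTurbid  7 0.9105245 6.7993692   FALSE
#>      pooled 60 0.9696038 3.9931464   FALSE
```

Each group reports n, R² and RMSE (mg m⁻³ here); at `noise_sd = 0` every
R² is exactly 1 by construction, which the test suite uses as its anchor.

A thin command-line wrapper with `classify`, `retrieve`, `validate` and
`simulate` subcommands ships in `inst/cli/lakeowt.R`.

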