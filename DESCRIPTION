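Package: lakeowt
Title: Optical Water Type Guided Water-Quality Retrieval for Boreal Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for optical water type (OWT) guided remote sensing of lake
    water quality. Resamples hyperspectral remote-sensing reflectance spectra
    to Sentinel-2 MSI and Sentinel-3 OLCI bands with spectral response
    functions, classifies per-band spectra into five boreal optical water
    types (Clear, Moderate, Turbid, Very Turbid, Brown) by combined spectral
    correlation and spectral angle similarity, and retrieves chlorophyll-a,
    total suspended matter, CDOM absorption, and Secchi depth through a
    declarative per-OWT algorithm registry, including a diffuse-attenuation
    (Kd490 to KdPAR) Secchi depth chain. Includes satellite versus in-situ
    match-up construction with R-squared/RMSE validation summaries and a
    semi-analytical bio-optical forward simulator that generates labelled
    spectra, scenes, and match-up tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
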