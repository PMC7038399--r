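#' Sensor band systems and spectral response functions
#'
#' A band set holds, per band, a name (`R<center>`), a nominal center
#' wavelength, and a tabulated spectral response function (SRF) as
#' (wavelength, weight) pairs. When only band centers and widths are known,
#' a Gaussian SRF is synthesized from the center and full width at half
#' maximum; measured SRFs can be supplied from a CSV table instead.
#'
#' @name bandset
NULL

# nominal centers (nm) and FWHM (nm) for the visible-NIR bands used here
.msi_bands <- data.frame(
  name   = c("R443", "R490", "R560", "R665", "R705", "R740", "R783", "R865"),
  center = c(442.7, 492.4, 559.8, 664.6, 704.1, 740.5, 782.8, 864.7),
  fwhm   = c(21, 66, 36, 31, 15, 15, 20, 21)
)

.olci_bands <- data.frame(
  name   = c("R400", "R412", "R443", "R490", "R510", "R560", "R620",
             "R665", "R674", "R681", "R709", "R754", "R779", "R865"),
  center = c(400, 412.5, 442.5, 490, 510, 560, 620,
             665, 673.75, 681.25, 709.5, 753.75, 778.75, 865),
  fwhm   = c(15, 10, 10, 10, 10, 10, 10, 10, 7.5, 7.5, 10, 7.5, 15, 20)
)

gaussian_srf <- function(center, fwhm, n = 61L) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  wl <- seq(center - 3 * sigma, center + 3 * sigma, length.out = n)
  data.frame(wavelength = wl, weight = exp(-0.5 * ((wl - center) / sigma)^2))
}

#' Construct a sensor band set
#'
#' `band_set("MSI")` and `band_set("OLCI")` return the builtin visible-NIR
#' band systems with Gaussian SRFs synthesized from nominal band centers and
#' widths. The OLCI 709.5, 673.75 and 681.25 nm bands are keyed by their
#' integer centers (`R709`, `R674`, `R681`).
#'
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param srf optional data.frame (band, wavelength, weight) of measured
#'   SRFs overriding the Gaussian defaults; band names must match.
#' @return An object of class `owt_bandset`: list(sensor, bands, srf).
#' @export
band_set <- function(sensor = c("MSI", "OLCI"), srf = NULL) {
  sensor <- match.arg(sensor)
  bands <- if (sensor == "MSI") .msi_bands else .olci_bands
  srfs <- lapply(seq_len(nrow(bands)), function(i) {
    gaussian_srf(bands$center[i], bands$fwhm[i])
  })
  names(srfs) <- bands$name
  if (!is.null(srf)) {
    stopifnot(all(c("band", "wavelength", "weight") %in% names(srf)))
    for (bn in unique(srf$band)) {
      if (!bn %in% bands$name) {
        stop(sprintf("SRF table names unknown band '%s'", bn))
      }
      sub <- srf[srf$band == bn, c("wavelength", "weight")]
      sub <- sub[order(sub$wavelength), ]
      if (any(sub$weight < 0) || all(sub$weight <= 0)) {
        stop(sprintf("SRF for band '%s' must be non-negative with a positive part", bn))
      }
      srfs[[bn]] <- sub
    }
  }
  structure(list(sensor = sensor, bands = bands, srf = srfs),
            class = "owt_bandset")
}

#' @export
print.owt_bandset <- function(x, ...) {
  cat(sprintf("<owt_bandset> %s: %s\n", x$sensor,
              paste(x$bands$name, collapse = " ")))
  invisible(x)
}

#' Band names of a band set
#' @param bands an `owt_bandset`.
#' @return character vector of band names ordered by center wavelength.
#' @export
band_names <- function(bands) bands$bands$name

# trapezoid integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Resample a hyperspectral spectrum to sensor bands
#'
#' Each band value is the SRF-weighted mean of the linearly interpolated
#' reflectance: integral of SRF(lambda) R(lambda) over the SRF support
#' divided by the integral of the SRF, both by trapezoid rule on the union
#' of the SRF and spectrum wavelength grids. SRF weights are therefore
#' normalized internally; the operation is exact for constants and linear
#' in the spectrum.
#'
#' @param s a hyperspectral `owt_spectrum` covering every band's SRF
#'   support.
#' @param bands an `owt_bandset`.
#' @return A per-band `owt_spectrum` (wavelengths = band centers, ordered),
#'   with `band_names` set and the sensor taken from `bands`.
#' @export
resample_to_bands <- function(s, bands) {
  stopifnot(inherits(s, "owt_spectrum"), inherits(bands, "owt_bandset"))
  wmin <- min(s$wavelengths); wmax <- max(s$wavelengths)
  vals <- vapply(bands$bands$name, function(bn) {
    srf <- bands$srf[[bn]]
    pos <- srf$wavelength[srf$weight > 0]
    if (min(pos) < wmin || max(pos) > wmax) {
      stop(sprintf("band %s SRF support [%.1f, %.1f] nm outside spectrum range [%.1f, %.1f] nm",
                   bn, min(pos), max(pos), wmin, wmax))
    }
    if (nrow(srf) == 1L) {
      # delta kernel: plain interpolation at the single SRF wavelength
      return(stats::approx(s$wavelengths, s$values, xout = srf$wavelength)$y)
    }
    grid <- sort(unique(c(
      srf$wavelength,
      s$wavelengths[s$wavelengths >= min(srf$wavelength) &
                    s$wavelengths <= max(srf$wavelength)]
    )))
    w <- stats::approx(srf$wavelength, srf$weight, xout = grid)$y
    r <- stats::approx(s$wavelengths, s$values, xout = grid)$y
    .trapz(grid, w * r) / .trapz(grid, w)
  }, numeric(1))
  ord <- order(bands$bands$center)
  owt_spectrum(bands$bands$center[ord], vals[ord],
               source = s$source, sensor = bands$sensor,
               band_names = bands$bands$name[ord])
}
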