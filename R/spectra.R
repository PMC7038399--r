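#' Remote-sensing reflectance spectrum
#'
#' Container for a wavelength-indexed remote-sensing reflectance vector,
#' either hyperspectral or already resampled to a sensor's bands.
#' Reflectance is the dimensionless ratio of water-leaving radiance to the
#' radiance of a white reference panel; no pi scaling is applied anywhere in
#' this package. Negative reflectances (possible after atmospheric
#' correction) are retained and flagged, never clipped.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values numeric vector of reflectances, same length as
#'   `wavelengths`, all finite.
#' @param source one of `"insitu"`, `"TOA"`, `"C2RCC"`, `"C2X"`.
#' @param sensor one of `"hyperspectral"`, `"MSI"`, `"OLCI"`.
#' @param band_names optional character vector of band names (e.g.
#'   `"R705"`) for per-band spectra.
#' @return An object of class `owt_spectrum`: a list with elements
#'   `wavelengths`, `values`, `source`, `sensor`, `band_names`, and
#'   `any_negative` (TRUE if any reflectance is below zero).
#' @export
owt_spectrum <- function(wavelengths, values,
                         source = c("insitu", "TOA", "C2RCC", "C2X"),
                         sensor = c("hyperspectral", "MSI", "OLCI"),
                         band_names = NULL) {
  source <- match.arg(source)
  sensor <- match.arg(sensor)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least 2 samples")
  }
  if (anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop("wavelengths must be finite")
  }
  if (any(diff(wavelengths) <= 0)) {
    dup <- wavelengths[which(diff(wavelengths) == 0)[1] + 1L]
    if (anyDuplicated(wavelengths)) {
      stop(sprintf("duplicated wavelength %g nm", dup))
    }
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(values))) {
    stop("reflectance values must be finite")
  }
  if (!is.null(band_names) && length(band_names) != length(values)) {
    stop("band_names must match values in length")
  }
  structure(
    list(
      wavelengths = wavelengths,
      values = values,
      source = source,
      sensor = sensor,
      band_names = band_names,
      any_negative = any(values < 0)
    ),
    class = "owt_spectrum"
  )
}

#' @export
print.owt_spectrum <- function(x, ...) {
  cat(sprintf(
    "<owt_spectrum> %s/%s, %d samples, %g-%g nm%s\n",
    x$sensor, x$source, length(x$values),
    min(x$wavelengths), max(x$wavelengths),
    if (x$any_negative) " [negative reflectances flagged]" else ""
  ))
  invisible(x)
}

#' @export
length.owt_spectrum <- function(x) length(x$values)

#' Read reflectance spectra from a delimited table
#'
#' The table must have one wavelength column (named by `wavelength_col`, or
#' the first column) and one or more value columns; each value column
#' becomes one spectrum sharing the wavelength axis. Wavelengths are sorted
#' if necessary (with a warning); duplicated wavelengths are an error.
#'
#' @param path path to a CSV file.
#' @param source,sensor passed to [owt_spectrum()].
#' @param wavelength_col name of the wavelength column; default the first.
#' @param sep field separator.
#' @return A named list of `owt_spectrum`, one per value column.
#' @export
read_spectra <- function(path, source = "insitu", sensor = "hyperspectral",
                         wavelength_col = NULL, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("spectra table needs a wavelength column and at least one value column")
  if (is.null(wavelength_col)) wavelength_col <- names(tab)[1L]
  if (!wavelength_col %in% names(tab)) {
    stop(sprintf("wavelength column '%s' not found", wavelength_col))
  }
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric cell in column '%s', row %d",
                   names(tab)[j], if (is.na(bad)) NA_integer_ else bad))
    }
  }
  wl <- tab[[wavelength_col]]
  if (anyDuplicated(wl)) {
    stop(sprintf("duplicated wavelength %g nm in '%s'",
                 wl[duplicated(wl)][1], path))
  }
  if (is.unsorted(wl)) {
    warning("wavelengths were not sorted; sorting")
    ord <- order(wl)
    tab <- tab[ord, , drop = FALSE]
    wl <- wl[ord]
  }
  value_cols <- setdiff(names(tab), wavelength_col)
  out <- lapply(value_cols, function(nm) {
    owt_spectrum(wl, tab[[nm]], source = source, sensor = sensor)
  })
  names(out) <- value_cols
  out
}

#' Write an observation table to CSV at full double precision
#'
#' Numeric columns are formatted with 17 significant digits so that a
#' write/read round trip reproduces every value bit-for-bit.
#'
#' @param obs a data.frame.
#' @param path output path.
#' @export
write_observations <- function(obs, path) {
  fmt <- obs
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), NA,
                         sprintf("%.17g", fmt[[j]]))
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read an observation table written by [write_observations()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_observations <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
}

#' Look up a band reflectance or processor product on an observation row
#'
#' Column naming convention is `<SOURCE>_R<center>` for band reflectances
#' (e.g. `TOA_R705`) and `<SOURCE>_<field>` for processor product fields
#' (e.g. `C2RCC_conc_tsm`). A present-but-empty cell and an absent optional
#' field both return `NA_real_`, never a silent zero. Requesting C2X from an
#' OLCI observation is an error: the C2X processor is not available for
#' OLCI.
#'
#' @param obs a one-row data.frame or a per-band `owt_spectrum`.
#' @param source reflectance source (`"TOA"`, `"C2RCC"`, `"C2X"`).
#' @param name band name (`"R705"`) or field name (`"conc_tsm"`).
#' @param sensor sensor of the observation, used to validate the request.
#' @return scalar reflectance/field value, or `NA_real_` if missing.
#' @export
band_value <- function(obs, source, name, sensor = NULL) {
  if (!is.null(sensor) && sensor == "OLCI" && source == "C2X") {
    stop("C2X reflectances are not available for OLCI (only C2RCC)")
  }
  if (inherits(obs, "owt_spectrum")) {
    if (is.null(obs$band_names)) stop("spectrum has no band names; resample first")
    i <- match(name, obs$band_names)
    if (is.na(i)) {
      stop(sprintf("unknown band '%s'; available: %s", name,
                   paste(obs$band_names, collapse = ", ")))
    }
    return(obs$values[i])
  }
  col <- paste0(source, "_", name)
  if (!col %in% names(obs)) {
    if (grepl("^R[0-9]+$", name)) {
      known <- if (is.null(sensor)) {
        unique(c(band_names(band_set("MSI")), band_names(band_set("OLCI"))))
      } else {
        band_names(band_set(sensor))
      }
      if (!name %in% known) {
        avail <- grep(paste0("^", source, "_R[0-9]+$"), names(obs), value = TRUE)
        stop(sprintf("unknown band '%s' for source %s; available: %s",
                     name, source,
                     paste(sub(paste0("^", source, "_"), "", avail),
                           collapse = ", ")))
      }
    }
    return(NA_real_)
  }
  as.numeric(obs[[col]][1])
}
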