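#' Per-OWT water-quality algorithm registry
#'
#' Each registry entry binds one (sensor, product, OWT) triple to a
#' retrieval rule: a reflectance source, a predictor expression over that
#' source's band reflectances (or a processor product field, or the
#' `kd490` operator), a response form (linear, quadratic, power, or
#' exponential) with its fitted coefficients, and the predictor domain on
#' which the response was fitted and is evaluated. The builtin registry
#' carries the best-performing model per OWT for both sensors:
#' 2 sensors x 4 products x 5 OWTs = 40 entries.
#'
#' Products and units: `chl` (mg m^-3), `tsm` (mg L^-1), `cdom400` (m^-1,
#' CDOM absorption at 400 nm), `sd` (m, Secchi depth).
#'
#' @name registry
NULL

.products <- c("chl", "tsm", "cdom400", "sd")
.sources <- c("TOA", "C2RCC", "C2X")
.external_fields <- c("conc_tsm", "conc_chl", "iop_agelb",
                      "Kd_489", "Kd_z90max")
.wide_domain <- c(-1e9, 1e9)

#' Construct a single algorithm specification
#'
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param product one of `"chl"`, `"tsm"`, `"cdom400"`, `"sd"`.
#' @param owt one of the five OWT labels.
#' @param source reflectance source the predictor reads from.
#' @param predictor expression string over band names (`"R705/R665"`), an
#'   external product field name (`"conc_tsm"`, `"Kd_489"`), or `"kd490"`
#'   for the diffuse-attenuation operator.
#' @param form `"linear"` (a*x + b), `"quadratic"` (a*x^2 + b*x + c),
#'   `"power"` (a*x^b), or `"exponential"` (a*exp(b*x)).
#' @param coef numeric coefficients, length 2 (linear/power/exponential)
#'   or 3 (quadratic), in the order written above.
#' @param domain length-2 numeric: predictor interval on which the
#'   response is evaluated; outside it the output is missing (the
#'   non-monotonic quadratic fits are only meaningful on the range they
#'   were calibrated over).
#' @param sample length-2 numeric: monotone predictor sub-interval used by
#'   the synthetic match-up generator.
#' @param note free-text provenance note.
#' @return object of class `owt_algorithm`.
#' @export
algorithm_spec <- function(sensor, product, owt, source, predictor, form,
                           coef, domain = NULL, sample = NULL, note = "") {
  stopifnot(sensor %in% c("MSI", "OLCI"),
            product %in% .products,
            owt %in% owt_levels(),
            source %in% .sources,
            form %in% c("linear", "quadratic", "power", "exponential"))
  if (sensor == "OLCI" && source == "C2X") {
    stop("C2X reflectances are not available for OLCI")
  }
  needed <- if (form == "quadratic") 3L else 2L
  if (length(coef) != needed) {
    stop(sprintf("%s form needs %d coefficients, got %d", form, needed,
                 length(coef)))
  }
  if (is.null(domain)) {
    domain <- if (form %in% c("power")) c(1e-9, 1e9) else .wide_domain
  }
  .validate_predictor(predictor, sensor)
  structure(list(sensor = sensor, product = product, owt = owt,
                 source = source, predictor = predictor, form = form,
                 coef = as.numeric(coef), domain = as.numeric(domain),
                 sample = if (is.null(sample)) NULL else as.numeric(sample),
                 note = note),
            class = "owt_algorithm")
}

.validate_predictor <- function(predictor, sensor) {
  if (predictor %in% c(.external_fields, "kd490")) return(invisible(TRUE))
  vars <- all.vars(parse(text = predictor)[[1]])
  known <- c(band_names(band_set(sensor)), .external_fields)
  bad <- setdiff(vars, known)
  if (length(bad) > 0) {
    stop(sprintf("predictor '%s' references unknown band(s) %s for %s",
                 predictor, paste(bad, collapse = ", "), sensor))
  }
  invisible(TRUE)
}

#' Human-readable formula of an algorithm spec
#' @param spec an `owt_algorithm`.
#' @return a string like `"y = 293.5x - 263.4 on TOA R705/R665"`.
#' @export
format_formula <- function(spec) {
  co <- spec$coef
  f <- switch(spec$form,
    linear = sprintf("y = %gx %s %g", co[1], ifelse(co[2] < 0, "-", "+"),
                     abs(co[2])),
    quadratic = sprintf("y = %gx^2 %s %gx %s %g", co[1],
                        ifelse(co[2] < 0, "-", "+"), abs(co[2]),
                        ifelse(co[3] < 0, "-", "+"), abs(co[3])),
    power = sprintf("y = %gx^%g", co[1], co[2]),
    exponential = sprintf("y = %ge^(%gx)", co[1], co[2])
  )
  sprintf("%s on %s %s", f, spec$source, spec$predictor)
}

#' @export
print.owt_algorithm <- function(x, ...) {
  cat(sprintf("<owt_algorithm> %s %s / %s: %s\n",
              x$sensor, x$product, x$owt, format_formula(x)))
  invisible(x)
}

.registry_key <- function(sensor, product, owt) {
  paste(sensor, product, owt, sep = ".")
}

.builtin_entries <- function() {
  A <- algorithm_spec
  list(
    ## chlorophyll-a (mg m^-3): red/NIR TOA band ratios for both sensors
    A("MSI", "chl", "Clear",      "TOA", "R740/R705 - R740/R665", "linear",
      c(-109.1, 20.32), sample = c(0.09, 0.17)),
    A("MSI", "chl", "Moderate",   "TOA", "R665/R705", "linear",
      c(-105.3, 140.6), sample = c(0.80, 1.25)),
    A("MSI", "chl", "Turbid",     "TOA", "R665/R705", "linear",
      c(104.5, -78.32), sample = c(0.85, 1.30)),
    A("MSI", "chl", "VeryTurbid", "TOA", "R740/R705 - R740/R665", "linear",
      c(-368.5, 39.1), sample = c(-0.15, 0.02)),
    A("MSI", "chl", "Brown",      "TOA", "R705/R665", "linear",
      c(293.5, -263.4), sample = c(0.94, 1.23)),
    A("OLCI", "chl", "Clear",      "TOA", "R709/R674", "linear",
      c(44.75, -32.78), sample = c(0.77, 0.97)),
    A("OLCI", "chl", "Moderate",   "TOA", "(R665 - R709)*R754", "linear",
      c(-21601, 23.78), sample = c(0.00004, 0.0008)),
    A("OLCI", "chl", "Turbid",     "TOA", "R709 - (R665 + R754)/2", "linear",
      c(1552.3, 21.03), sample = c(0.0005, 0.025)),
    A("OLCI", "chl", "VeryTurbid", "TOA", "R665/R709", "linear",
      c(-246.33, 291.75), sample = c(0.78, 1.06)),
    A("OLCI", "chl", "Brown",      "TOA", "R665/R709", "linear",
      c(-316.56, 365.88), sample = c(0.84, 1.12)),

    ## total suspended matter (mg L^-1)
    A("MSI", "tsm", "Clear",      "TOA", "R705", "linear",
      c(46.19, 0.15), sample = c(0.02, 0.13)),
    A("MSI", "tsm", "Moderate",   "C2RCC", "conc_tsm", "linear",
      c(-0.91, 39.29), sample = c(10, 40)),
    A("MSI", "tsm", "Turbid",     "C2RCC", "R705", "linear",
      c(531, 2.73), sample = c(0.004, 0.09)),
    A("MSI", "tsm", "VeryTurbid", "C2RCC", "conc_tsm", "linear",
      c(0.41, 0.05), sample = c(10, 60)),
    A("MSI", "tsm", "Brown",      "C2X", "R705", "linear",
      c(1144.9, -2.28), sample = c(0.0037, 0.028)),
    A("OLCI", "tsm", "Clear",      "C2RCC", "R620*R681/R510", "linear",
      c(267.97, 2.81), sample = c(0.0007, 0.019)),
    A("OLCI", "tsm", "Moderate",   "C2RCC", "R779 - R754 + R865/2", "linear",
      c(-13814, 17.65), sample = c(0.00005, 0.001)),
    A("OLCI", "tsm", "Turbid",     "TOA", "R620*R681/R510", "linear",
      c(496.38, -6.07), sample = c(0.0223, 0.113)),
    A("OLCI", "tsm", "VeryTurbid", "TOA", "R779 - R754 + R865/2", "linear",
      c(771.07, 3.35), sample = c(0.006, 0.041)),
    A("OLCI", "tsm", "Brown",      "TOA", "R709", "linear",
      c(529.77, -16.26), sample = c(0.035, 0.068)),

    ## CDOM absorption at 400 nm (m^-1)
    A("MSI", "cdom400", "Clear",      "C2RCC", "R665/R490", "linear",
      c(0.26, 1.56), sample = c(0.05, 0.90)),
    A("MSI", "cdom400", "Moderate",   "TOA", "R665/R490", "quadratic",
      c(81.28, -80.38, 23.91), domain = c(0.2, 1.2), sample = c(0.55, 0.85)),
    A("MSI", "cdom400", "Turbid",     "C2X", "R665/R560", "linear",
      c(21.31, -9.67), sample = c(0.50, 0.92)),
    A("MSI", "cdom400", "VeryTurbid", "TOA", "R665/R490", "quadratic",
      c(148.99, -203.38, 73.33), domain = c(0.3, 1.4), sample = c(0.70, 0.95)),
    A("MSI", "cdom400", "Brown",      "C2RCC", "R665/R490", "quadratic",
      c(6.43, -19.19, 20.27), domain = c(0.8, 2.5), sample = c(1.55, 2.2)),
    A("OLCI", "cdom400", "Clear",      "C2RCC", "R665/R560", "linear",
      c(7.035, 0.34), sample = c(0.094, 0.378),
      note = "published as R665/R550; encoded on the nearest green band (560 nm)"),
    A("OLCI", "cdom400", "Moderate",   "C2RCC", "R665/R490", "exponential",
      c(9.4, -0.67), domain = c(0, 5), sample = c(0.25, 1.70)),
    A("OLCI", "cdom400", "Turbid",     "TOA", "R620*R681/R510", "quadratic",
      c(1618.6, -225.9, 12.02), domain = c(0.005, 0.15),
      sample = c(0.0223, 0.113)),
    A("OLCI", "cdom400", "VeryTurbid", "TOA", "R620*R681/R510", "power",
      c(1.97, -0.4), domain = c(0.001, 2), sample = c(0.05, 0.30)),
    A("OLCI", "cdom400", "Brown",      "C2RCC", "R665/R490", "quadratic",
      c(8.83, -29.82, 33.17), domain = c(1.2, 2.6), sample = c(1.70, 2.30)),

    ## Secchi depth (m), mostly through the Kd490 operator
    A("MSI", "sd", "Clear",      "TOA", "kd490", "power",
      c(2.21, -1.42), domain = c(0.01, 20), sample = c(0.40, 0.80)),
    A("MSI", "sd", "Moderate",   "C2X", "Kd_489", "linear",
      c(-0.18, 1.44), sample = c(1.0, 4.5)),
    A("MSI", "sd", "Turbid",     "TOA", "kd490", "power",
      c(0.7, -0.9), domain = c(0.01, 20), sample = c(0.70, 2.20)),
    A("MSI", "sd", "VeryTurbid", "TOA", "kd490", "power",
      c(0.59, -1.56), domain = c(0.01, 20), sample = c(0.80, 1.50)),
    A("MSI", "sd", "Brown",      "C2X", "kd490", "linear",
      c(0.35, -1.23), sample = c(4.70, 6.90)),
    A("OLCI", "sd", "Clear",      "C2RCC", "kd490", "quadratic",
      c(0.37, -2.7, 5.63), domain = c(0.1, 3.0), sample = c(0.30, 1.50)),
    A("OLCI", "sd", "Moderate",   "C2RCC", "kd490", "quadratic",
      c(2.98, -8.32, 6.48), domain = c(0.3, 2.0), sample = c(0.60, 1.30)),
    A("OLCI", "sd", "Turbid",     "C2RCC", "Kd_489", "quadratic",
      c(0.17, -1.54, 4.07), domain = c(0.5, 4.5), sample = c(1.50, 4.00)),
    A("OLCI", "sd", "VeryTurbid", "TOA", "kd490", "power",
      c(0.5, -1.40), domain = c(0.01, 20), sample = c(0.80, 1.60)),
    A("OLCI", "sd", "Brown",      "TOA", "kd490", "power",
      c(0.54, -1.25), domain = c(0.01, 20), sample = c(0.90, 2.00))
  )
}

.make_registry <- function(entries) {
  keys <- vapply(entries, function(e) .registry_key(e$sensor, e$product, e$owt),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate registry entry for ", keys[duplicated(keys)][1])
  }
  names(entries) <- keys
  structure(list(entries = entries), class = "owt_registry")
}

#' The builtin per-OWT algorithm registry
#'
#' @return an `owt_registry` with all 40 (sensor, product, OWT) entries.
#' @export
builtin_registry <- function() .make_registry(.builtin_entries())

#' Load an algorithm registry
#'
#' `load_registry("builtin")` returns the builtin registry. A JSON path
#' loads a user configuration: a JSON array of entry objects with fields
#' `sensor`, `product`, `owt`, `source`, `predictor`, `form`, `coef`, and
#' optionally `domain`, `sample`, `note`. User entries override the
#' matching builtin entries when `base` is supplied (the default); pass
#' `base = NULL` to load the file standalone.
#'
#' @param config `"builtin"` or a JSON file path.
#' @param base registry whose entries the config overrides.
#' @return an `owt_registry`.
#' @export
load_registry <- function(config = "builtin", base = builtin_registry()) {
  if (identical(config, "builtin")) return(builtin_registry())
  raw <- jsonlite::read_json(config, simplifyVector = FALSE)
  entries <- lapply(raw, function(e) {
    algorithm_spec(e$sensor, e$product, e$owt, e$source, e$predictor,
                   e$form, unlist(e$coef),
                   domain = if (is.null(e$domain)) NULL else unlist(e$domain),
                   sample = if (is.null(e$sample)) NULL else unlist(e$sample),
                   note = if (is.null(e$note)) "" else e$note)
  })
  new <- .make_registry(entries)
  if (is.null(base)) return(new)
  merged <- base$entries
  merged[names(new$entries)] <- new$entries
  .make_registry(unname(merged))
}

#' Write a registry to JSON
#' @param registry an `owt_registry`.
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(registry$entries, function(e) {
    e[!vapply(e, is.null, logical(1))]
  })
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Look up a registry entry
#'
#' @param registry an `owt_registry`.
#' @param sensor,product,owt the triple to resolve.
#' @return the matching `owt_algorithm`.
#' @export
registry_lookup <- function(registry, sensor, product, owt) {
  key <- .registry_key(sensor, product, owt)
  e <- registry$entries[[key]]
  if (is.null(e)) stop("no registry entry for ", key)
  e
}

#' @export
print.owt_registry <- function(x, ...) {
  cat(sprintf("<owt_registry> %d entries\n", length(x$entries)))
  for (e in x$entries) cat(" ", format(format_formula(e)), "\n")
  invisible(x)
}
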