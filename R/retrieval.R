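#' Evaluate a predictor expression on an observation row
#'
#' Band tokens (`R705`, ...) are resolved to `<source>_R705` columns of the
#' observation row; external product fields (`conc_tsm`, `Kd_489`, ...) to
#' `<source>_<field>` columns; the special predictor `"kd490"` runs the
#' diffuse-attenuation operator [kd490()]. Missing inputs propagate to a
#' missing output (never a silent zero); division by zero or other
#' non-finite arithmetic yields `NA` with a `diagnostic` attribute.
#'
#' @param predictor predictor string (see [algorithm_spec()]).
#' @param obs one-row data.frame (observation-table naming convention).
#' @param source reflectance source to read bands from.
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param kd_model coefficients for the `kd490` operator, see
#'   [kd490_model()].
#' @return scalar predictor value, or `NA_real_`.
#' @export
eval_predictor <- function(predictor, obs, source, sensor,
                           kd_model = kd490_model()) {
  if (predictor == "kd490") {
    return(kd490(obs, sensor, source, model = kd_model))
  }
  if (predictor %in% .external_fields) {
    return(band_value(obs, source, predictor, sensor = sensor))
  }
  expr <- parse(text = predictor)[[1]]
  vars <- all.vars(expr)
  vals <- lapply(vars, function(v) band_value(obs, source, v, sensor = sensor))
  names(vals) <- vars
  if (any(vapply(vals, is.na, logical(1)))) return(NA_real_)
  out <- eval(expr, envir = vals)
  if (!is.finite(out)) {
    return(structure(NA_real_,
                     diagnostic = sprintf("non-finite predictor '%s' (division by zero?)",
                                          predictor)))
  }
  out
}

#' Evaluate a response form
#'
#' Closed-form evaluation of `y = a*x + b` (linear), `a*x^2 + b*x + c`
#' (quadratic), `a*x^b` (power), or `a*exp(b*x)` (exponential). Inputs
#' outside the spec's predictor domain, non-positive inputs to the power
#' form, and missing inputs all give `NA` (with a `diagnostic` attribute
#' where informative). Vectorized over `x`.
#'
#' @param form response form name, or an `owt_algorithm` (then `coef` and
#'   `domain` are taken from it).
#' @param x predictor value(s).
#' @param coef,domain coefficients and valid predictor interval.
#' @return product value(s) in the product's units.
#' @export
eval_response <- function(form, x, coef = NULL, domain = NULL) {
  if (inherits(form, "owt_algorithm")) {
    coef <- form$coef
    domain <- form$domain
    form <- form$form
  }
  if (is.null(domain)) domain <- .wide_domain
  x <- as.numeric(x)
  ok <- !is.na(x) & x >= domain[1] & x <= domain[2]
  if (form == "power") ok <- ok & !is.na(x) & x > 0
  y <- rep(NA_real_, length(x))
  xi <- x[ok]
  y[ok] <- switch(form,
    linear      = coef[1] * xi + coef[2],
    quadratic   = coef[1] * xi^2 + coef[2] * xi + coef[3],
    power       = coef[1] * xi^coef[2],
    exponential = coef[1] * exp(coef[2] * xi),
    stop("unknown response form: ", form)
  )
  if (any(!ok & !is.na(x))) {
    attr(y, "diagnostic") <- sprintf(
      "%d input(s) outside the valid predictor domain [%g, %g]",
      sum(!ok & !is.na(x)), domain[1], domain[2])
  }
  y
}

#' Coefficients of the Kd490 band model
#'
#' The diffuse attenuation coefficient at 490 nm is modelled log-linearly
#' in log10 band ratios:
#' `Kd490 = 10^(a0 + a1*log10(R490/R560) + a2*log10(Rred/R560))`,
#' where the red band is 705 nm for MSI and 709.5 nm for OLCI. The default
#' coefficients are documented placeholders chosen to give plausible
#' boreal-lake magnitudes (roughly 0.2 m^-1 in clear water to several
#' m^-1 in turbid water) and to be monotone increasing in the red band;
#' they are not the published calibration, which users can substitute here.
#'
#' @param a0,a1,a2 model coefficients.
#' @return list of class `kd490_model`.
#' @export
kd490_model <- function(a0 = 0.05, a1 = -1.2, a2 = 1.0) {
  structure(list(a0 = a0, a1 = a1, a2 = a2), class = "kd490_model")
}

#' Diffuse attenuation coefficient at 490 nm from band reflectances
#'
#' Reads R490, R560 and the sensor's red-edge band (R705 for MSI, R709 for
#' OLCI) from the observation row and applies the [kd490_model()]. A
#' non-positive reflectance under the logarithm gives `NA` with a
#' diagnostic.
#'
#' @param obs one-row data.frame.
#' @param sensor `"MSI"` or `"OLCI"` (selects the red band).
#' @param source reflectance source.
#' @param model a [kd490_model()].
#' @return Kd490 in m^-1 (positive), or `NA_real_`.
#' @export
kd490 <- function(obs, sensor, source, model = kd490_model()) {
  red <- if (sensor == "OLCI") "R709" else "R705"
  r490 <- band_value(obs, source, "R490", sensor = sensor)
  r560 <- band_value(obs, source, "R560", sensor = sensor)
  rred <- band_value(obs, source, red, sensor = sensor)
  kd490_from_bands(r490, r560, rred, model = model)
}

#' @rdname kd490
#' @param r490,r560,rred band reflectances at 490, 560 and the red-edge
#'   wavelength.
#' @export
kd490_from_bands <- function(r490, r560, rred, model = kd490_model()) {
  if (anyNA(c(r490, r560, rred))) return(NA_real_)
  if (r490 <= 0 || r560 <= 0 || rred <= 0) {
    return(structure(NA_real_,
                     diagnostic = "non-positive reflectance under log in Kd490 model"))
  }
  10^(model$a0 + model$a1 * log10(r490 / r560) + model$a2 * log10(rred / r560))
}

#' Kd490 to KdPAR to Secchi depth chain
#'
#' `kd_par()` converts the diffuse attenuation at 490 nm to the
#' photosynthetically-active-range attenuation:
#' `KdPAR = 0.4349 * Kd490 + 0.3291` (m^-1, strictly increasing).
#' `secchi_from_kdpar()` converts KdPAR to Secchi depth:
#' `SD = 1.6941 * KdPAR^-0.677` (m, strictly decreasing).
#'
#' @param kd490 diffuse attenuation at 490 nm (m^-1).
#' @return KdPAR in m^-1.
#' @export
kd_par <- function(kd490) 0.4349 * kd490 + 0.3291

#' @rdname kd_par
#' @param kdpar diffuse attenuation over 400-700 nm (m^-1), positive.
#' @return Secchi depth in m.
#' @export
secchi_from_kdpar <- function(kdpar) {
  out <- rep(NA_real_, length(kdpar))
  ok <- !is.na(kdpar) & kdpar > 0
  out[ok] <- 1.6941 * kdpar[ok]^(-0.677)
  out
}

#' Convert CDOM absorption between reference wavelengths
#'
#' Exponential spectral-slope model:
#' `a_CDOM(lambda) = a_CDOM(400) * exp(-S * (lambda - 400))`.
#'
#' @param cdom400 absorption at 400 nm (m^-1).
#' @param wavelength target wavelength in nm (e.g. 412, 442).
#' @param slope spectral slope S in nm^-1 (default 0.018).
#' @return absorption at `wavelength` (m^-1).
#' @export
cdom_at <- function(cdom400, wavelength, slope = 0.018) {
  cdom400 * exp(-slope * (wavelength - 400))
}

#' Retrieve all water-quality products for one observation
#'
#' Applies the (sensor, product, OWT) registry entry for each of the four
#' products to one observation row. An `"Unclassified"` OWT yields all
#' products missing with a reason; a missing input leaves only the
#' affected product missing.
#'
#' @param obs one-row data.frame in the observation naming convention.
#' @param owt OWT label guiding the algorithm choice.
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param registry an `owt_registry` (default builtin).
#' @param kd_model coefficients for the `kd490` operator.
#' @return one-row data.frame with columns `chl`, `tsm`, `cdom400`, `sd`
#'   and a `provenance` attribute: per product the source and formula that
#'   produced it.
#' @export
retrieve <- function(obs, owt, sensor, registry = builtin_registry(),
                     kd_model = kd490_model()) {
  out <- stats::setNames(as.list(rep(NA_real_, length(.products))), .products)
  if (is.na(owt) || owt == "Unclassified") {
    res <- as.data.frame(out)
    attr(res, "provenance") <- list(reason = "OWT is Unclassified; no algorithm applies")
    return(res)
  }
  prov <- list()
  for (product in .products) {
    spec <- registry_lookup(registry, sensor, product, owt)
    x <- eval_predictor(spec$predictor, obs, spec$source, sensor,
                        kd_model = kd_model)
    y <- if (is.na(x)) NA_real_ else as.numeric(eval_response(spec, x))
    out[[product]] <- y
    prov[[product]] <- list(source = spec$source, predictor = spec$predictor,
                            formula = format_formula(spec),
                            predictor_value = as.numeric(x))
  }
  res <- as.data.frame(out)
  attr(res, "provenance") <- prov
  res
}

#' Retrieve products for every row of an observation table
#'
#' @param obs data.frame of observations.
#' @param owt character vector of OWT labels (length 1 or `nrow(obs)`), or
#'   the name of a column of `obs` holding them.
#' @inheritParams retrieve
#' @return data.frame with columns `derived_chl`, `derived_tsm`,
#'   `derived_cdom400`, `derived_sd` bound after the input columns.
#' @export
retrieve_table <- function(obs, owt, sensor, registry = builtin_registry(),
                           kd_model = kd490_model()) {
  if (length(owt) == 1L && owt %in% names(obs)) owt <- obs[[owt]]
  owt <- rep_len(as.character(owt), nrow(obs))
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    retrieve(obs[i, , drop = FALSE], owt[i], sensor, registry, kd_model)
  })
  derived <- do.call(rbind, rows)
  names(derived) <- paste0("derived_", names(derived))
  cbind(obs, derived, row.names = NULL)
}

#' Retrieve product grids for a classified scene
#'
#' Per-pixel application of [retrieve()] to gridded band stacks.
#' `stacks` is a named list keyed by reflectance source (`"TOA"`,
#' `"C2RCC"`, `"C2X"`), each a 3-d array `[row, col, band]` with band
#' names; entries whose source is absent yield missing pixels, as do
#' Unclassified labels.
#'
#' @param stacks named list of band stacks by source, or a single stack
#'   (then `source` names it).
#' @param labels character matrix of OWT labels aligned to the grid.
#' @param sensor,registry,kd_model as in [retrieve()].
#' @param source source name when `stacks` is a single array.
#' @return named list of numeric matrices, one per product.
#' @export
retrieve_scene <- function(stacks, labels, sensor,
                           registry = builtin_registry(),
                           kd_model = kd490_model(), source = "TOA") {
  if (is.array(stacks) && length(dim(stacks)) == 3L) {
    stacks <- stats::setNames(list(stacks), source)
  }
  d <- dim(stacks[[1]])[1:2]
  if (!all(dim(labels) == d)) {
    stop("labels grid does not match the stack dimensions")
  }
  for (s in stacks) {
    if (!all(dim(s)[1:2] == d)) stop("all stacks must share grid dimensions")
  }
  grids <- lapply(.products, function(p) matrix(NA_real_, d[1], d[2]))
  names(grids) <- .products
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      row <- list()
      for (src in names(stacks)) {
        bn <- dimnames(stacks[[src]])[[3]]
        vals <- stacks[[src]][i, j, ]
        row[paste0(src, "_", bn)] <- vals
      }
      row <- as.data.frame(row, check.names = FALSE)
      res <- retrieve(row, labels[i, j], sensor, registry, kd_model)
      for (p in .products) grids[[p]][i, j] <- res[[p]]
    }
  }
  grids
}
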