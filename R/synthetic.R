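#' Synthetic bio-optical data generation
#'
#' A deliberately simple semi-analytical forward model stands in for
#' unreleased field spectra: remote-sensing reflectance is
#' `R(lambda) = f * bb / (a + bb)` with total absorption
#' `a = aw + chl * aph* + cdom400 * exp(-S (lambda - 400)) + aNAP` and
#' total backscatter `bb = bbw + bbp(tsm)`. The five OWT archetypes are
#' parameterized so each class's qualitative reflectance features emerge
#' from its dominant constituent (TSM for Turbid, Chl-a for VeryTurbid,
#' CDOM for Brown, ...). All shape tables live in [bio_optical_coeffs()].
#'
#' @name synthetic
NULL

# run expr under a temporary RNG seed, restoring global RNG state after
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Bio-optical parameter set driving the forward model
#'
#' @param chl chlorophyll-a, mg m^-3 (>= 0).
#' @param tsm total suspended matter, mg L^-1 (>= 0).
#' @param cdom400 CDOM absorption at 400 nm, m^-1 (>= 0).
#' @param s_cdom CDOM spectral slope, nm^-1, in (0.005, 0.03).
#' @return list of class `bio_optical_params`.
#' @export
bio_optical_params <- function(chl, tsm, cdom400, s_cdom = 0.018) {
  stopifnot(chl >= 0, tsm >= 0, cdom400 >= 0,
            s_cdom > 0.005, s_cdom < 0.03)
  structure(list(chl = chl, tsm = tsm, cdom400 = cdom400, s_cdom = s_cdom),
            class = "bio_optical_params")
}

#' Forward-model coefficient tables
#'
#' Pure-water absorption `aw` (m^-1, tabulated 380-900 nm, linearly
#' interpolated), chlorophyll-specific absorption shape with peaks near
#' 440 and 675 nm (m^2 mg^-1), non-algal-particle absorption per TSM with
#' an exponential slope, pure-water and particulate backscatter, and the
#' proportionality factor `f` relating reflectance to `bb/(a+bb)`. All
#' shapes are non-negative over 380-900 nm.
#'
#' @return list of class `bio_optical_coeffs`.
#' @export
bio_optical_coeffs <- function() {
  structure(list(
    aw_wl = c(380, 390, 400, 420, 440, 460, 480, 490, 500, 520, 540, 560, 580, 600,
              620, 640, 660, 665, 680, 700, 710, 720, 740, 750, 760, 780,
              800, 820, 840, 860, 880, 900),
    aw = c(0.01137, 0.00851, 0.00663, 0.00473, 0.00635, 0.00922, 0.0127, 0.015, 0.0204,
           0.0409, 0.0474, 0.0619, 0.0893, 0.2224, 0.2755, 0.3292, 0.4064,
           0.429, 0.465, 0.624, 0.829, 1.169, 2.38, 2.47, 2.55, 2.51,
           2.07, 2.82, 4.26, 4.56, 5.51, 6.78),
    # chl-specific absorption: blue and red peaks plus a green shoulder
    # (accessory pigments), each as (center nm, sigma nm, amplitude m^2/mg)
    aph_peaks = list(c(440, 30, 0.035), c(675, 15, 0.022), c(550, 90, 0.015)),
    nap_a440 = 0.03,       # m^2 g^-1 at 440 nm
    nap_slope = 0.011,     # nm^-1
    bbp_star = 0.012,      # m^2 g^-1 particulate backscatter at 555 nm
    bbp_exp = 0.7,         # wavelength exponent, (555/lambda)^exp
    bbw_500 = 0.0011,      # m^-1 pure-water backscatter at 500 nm
    bbw_exp = 4.3,
    f = 0.17               # reflectance proportionality factor
  ), class = "bio_optical_coeffs")
}

.aph_star <- function(wl, coeffs) {
  Reduce(`+`, lapply(coeffs$aph_peaks, function(p) {
    p[3] * exp(-0.5 * ((wl - p[1]) / p[2])^2)
  }))
}

#' Simulate a remote-sensing reflectance spectrum
#'
#' @param params a [bio_optical_params()].
#' @param coeffs a [bio_optical_coeffs()].
#' @param wavelengths nm, within the coefficient tables' support
#'   (400-900 nm).
#' @return a hyperspectral `owt_spectrum` (source `"insitu"`), strictly
#'   positive.
#' @export
forward_rrs <- function(params, coeffs = bio_optical_coeffs(),
                        wavelengths = seq(380, 900, by = 2.5)) {
  wl <- wavelengths
  if (min(wl) < min(coeffs$aw_wl) || max(wl) > max(coeffs$aw_wl)) {
    stop("wavelengths outside the coefficient tables' support")
  }
  aw <- stats::approx(coeffs$aw_wl, coeffs$aw, xout = wl)$y
  a <- aw +
    params$chl * .aph_star(wl, coeffs) +
    params$cdom400 * exp(-params$s_cdom * (wl - 400)) +
    params$tsm * coeffs$nap_a440 * exp(-coeffs$nap_slope * (wl - 440))
  bb <- coeffs$bbw_500 * (500 / wl)^coeffs$bbw_exp +
    params$tsm * coeffs$bbp_star * (555 / wl)^coeffs$bbp_exp
  owt_spectrum(wl, coeffs$f * bb / (a + bb), source = "insitu",
               sensor = "hyperspectral")
}

# central archetype parameters per OWT; regimes follow the four study
# lakes (clear oligotrophic, mixed eutrophic, TSM-dominated shallow,
# bloom-dominated, CDOM-rich)
.archetype_centers <- list(
  Clear      = list(chl = 5,  tsm = 1.7, cdom400 = 1.6),
  Moderate   = list(chl = 15, tsm = 8,   cdom400 = 3.5),
  Turbid     = list(chl = 20, tsm = 30,  cdom400 = 3.5),
  VeryTurbid = list(chl = 110, tsm = 15, cdom400 = 3.0),
  Brown      = list(chl = 10, tsm = 5,   cdom400 = 8.0)
)

#' Draw a bio-optical archetype for an optical water type
#'
#' Parameters are drawn log-normally around the class centers
#' (`sdlog = jitter`); class-defining floors are enforced afterwards
#' (VeryTurbid chl >= 30 mg m^-3, Brown cdom400 >= 5 m^-1). `jitter = 0`
#' returns the class center exactly.
#'
#' @param owt one of the five OWT labels.
#' @param seed optional integer; the global RNG state is restored after.
#' @param jitter log-normal sdlog of the parameter draw.
#' @param coeffs forward-model coefficients.
#' @param wavelengths hyperspectral grid for the returned spectrum.
#' @return list with `params` (a [bio_optical_params()]) and `spectrum`
#'   (hyperspectral `owt_spectrum`).
#' @export
generate_archetype <- function(owt, seed = NULL, jitter = 0.25,
                               coeffs = bio_optical_coeffs(),
                               wavelengths = seq(380, 900, by = 2.5)) {
  if (!owt %in% owt_levels()) stop("owt must be one of the five OWT labels")
  .with_seed(seed, {
    ctr <- .archetype_centers[[owt]]
    mult <- if (jitter > 0) stats::rlnorm(3, 0, jitter) else rep(1, 3)
    chl <- ctr$chl * mult[1]
    tsm <- ctr$tsm * mult[2]
    cdom <- ctr$cdom400 * mult[3]
    if (owt == "VeryTurbid") chl <- max(chl, 30)
    if (owt == "Brown") cdom <- max(cdom, 5)
    params <- bio_optical_params(chl, tsm, cdom)
    list(params = params, spectrum = forward_rrs(params, coeffs, wavelengths))
  })
}

# map a water-leaving reflectance spectrum to a source's convention:
# C2RCC systematically underestimates, C2X is close to truth, TOA adds a
# Rayleigh-like path-reflectance term decreasing with wavelength
.source_spectrum <- function(s, source) {
  v <- switch(source,
    insitu = s$values,
    C2RCC = 0.85 * s$values,
    C2X = 0.95 * s$values,
    TOA = s$values + 0.09 * (450 / s$wavelengths)^3.5,
    stop("unknown source ", source)
  )
  owt_spectrum(s$wavelengths, v, source = source, sensor = s$sensor)
}

#' Shipped default reference library
#'
#' Per-band reference spectra for the five OWTs, computed from the
#' noise-free archetype centers through the forward model and the sensor's
#' SRFs. These are synthetic stand-ins documented as such; use
#' [read_reference_library()] to substitute a published reference set.
#'
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param threshold unclassified threshold.
#' @return an `owt_reference_library`.
#' @export
default_reference_library <- function(sensor = c("MSI", "OLCI"),
                                      threshold = 0.8) {
  sensor <- match.arg(sensor)
  bands <- band_set(sensor)
  refs <- lapply(owt_levels(), function(owt) {
    arch <- generate_archetype(owt, jitter = 0)
    pb <- resample_to_bands(arch$spectrum, bands)
    stats::setNames(pb$values, pb$band_names)
  })
  names(refs) <- owt_levels()
  reference_library(sensor, refs, threshold = threshold)
}

# sources simulated for each sensor (C2X exists only for MSI)
.sensor_sources <- function(sensor) {
  if (sensor == "MSI") c("TOA", "C2RCC", "C2X") else c("TOA", "C2RCC")
}

# one observation row of per-band reflectances for all of a sensor's
# sources, derived from a single water-leaving spectrum
.observation_row <- function(spectrum, sensor) {
  bands <- band_set(sensor)
  row <- list()
  for (src in .sensor_sources(sensor)) {
    pb <- resample_to_bands(.source_spectrum(spectrum, src), bands)
    row[paste0(src, "_", pb$band_names)] <- as.list(pb$values)
  }
  row
}

# --- band solving -----------------------------------------------------------
# Adjust bands of an observation row so that each product's registry
# predictor evaluates exactly to its target value x. Steps are ordered per
# (sensor, OWT) so that later solves never disturb earlier ones.

.g <- function(row, col) row[[col]]

.solve_kd <- function(row, src, sensor, kd, model, via = c("R490", "Rred")) {
  via <- match.arg(via)
  red <- if (sensor == "OLCI") "R709" else "R705"
  r490 <- .g(row, paste0(src, "_R490"))
  r560 <- .g(row, paste0(src, "_R560"))
  rred <- .g(row, paste0(src, "_", red))
  q <- kd / 10^model$a0
  if (via == "R490") {
    row[[paste0(src, "_R490")]] <- r560 * (q * (rred / r560)^(-model$a2))^(1 / model$a1)
  } else {
    row[[paste0(src, "_", red)]] <- r560 * (q * (r490 / r560)^(-model$a1))^(1 / model$a2)
  }
  row
}

.solve_bands <- function(row, sensor, owt, x, kd_model) {
  set <- function(col, val) row[[col]] <<- val
  if (sensor == "MSI") {
    switch(owt,
      Clear = {
        set("TOA_R705", x$tsm)
        set("TOA_R740", x$chl / (1 / row$TOA_R705 - 1 / row$TOA_R665))
        set("C2RCC_R490", row$C2RCC_R665 / x$cdom400)
        row <- .solve_kd(row, "TOA", sensor, x$sd, kd_model, "R490")
      },
      Moderate = {
        set("TOA_R705", row$TOA_R665 / x$chl)
        set("C2RCC_conc_tsm", x$tsm)
        set("TOA_R490", row$TOA_R665 / x$cdom400)
        set("C2X_Kd_489", x$sd)
      },
      Turbid = {
        set("TOA_R705", row$TOA_R665 / x$chl)
        set("C2RCC_R705", x$tsm)
        set("C2X_R560", row$C2X_R665 / x$cdom400)
        row <- .solve_kd(row, "TOA", sensor, x$sd, kd_model, "R490")
      },
      VeryTurbid = {
        set("TOA_R490", row$TOA_R665 / x$cdom400)
        row <- .solve_kd(row, "TOA", sensor, x$sd, kd_model, "Rred")
        set("TOA_R740", x$chl / (1 / row$TOA_R705 - 1 / row$TOA_R665))
        set("C2RCC_conc_tsm", x$tsm)
      },
      Brown = {
        set("C2X_R705", x$tsm)
        set("TOA_R705", x$chl * row$TOA_R665)
        set("C2RCC_R490", row$C2RCC_R665 / x$cdom400)
        row <- .solve_kd(row, "C2X", sensor, x$sd, kd_model, "R490")
      })
  } else {
    switch(owt,
      Clear = {
        set("TOA_R709", x$chl * row$TOA_R674)
        set("C2RCC_R620", x$tsm * row$C2RCC_R510 / row$C2RCC_R681)
        set("C2RCC_R665", x$cdom400 * row$C2RCC_R560)
        row <- .solve_kd(row, "C2RCC", sensor, x$sd, kd_model, "R490")
      },
      Moderate = {
        set("TOA_R665", row$TOA_R709 + x$chl / row$TOA_R754)
        set("C2RCC_R779", x$tsm + row$C2RCC_R754 - row$C2RCC_R865 / 2)
        set("C2RCC_R490", row$C2RCC_R665 / x$cdom400)
        row <- .solve_kd(row, "C2RCC", sensor, x$sd, kd_model, "Rred")
      },
      Turbid = {
        set("TOA_R709", x$chl + (row$TOA_R665 + row$TOA_R754) / 2)
        set("TOA_R620", x$tsm * row$TOA_R510 / row$TOA_R681)
        set("C2RCC_Kd_489", x$sd)
      },
      VeryTurbid = {
        set("TOA_R709", row$TOA_R665 / x$chl)
        set("TOA_R620", x$cdom400 * row$TOA_R510 / row$TOA_R681)
        set("TOA_R779", x$tsm + row$TOA_R754 - row$TOA_R865 / 2)
        row <- .solve_kd(row, "TOA", sensor, x$sd, kd_model, "R490")
      },
      Brown = {
        set("TOA_R709", x$tsm)
        set("TOA_R665", x$chl * row$TOA_R709)
        set("C2RCC_R490", row$C2RCC_R665 / x$cdom400)
        row <- .solve_kd(row, "TOA", sensor, x$sd, kd_model, "R490")
      })
  }
  row
}

#' Generate synthetic satellite-in-situ match-up tables
#'
#' For each record an OWT and bio-optical archetype are drawn; per-band
#' reflectances for every source are simulated through the forward model,
#' then adjusted so that the predictor of the governing registry entry for
#' each product evaluates exactly to a value sampled on that entry's
#' monotone predictor branch. The in-situ truth is the registry formula
#' applied to that predictor value, so at `noise_sd = 0` retrieval
#' reproduces the in-situ products exactly; relative Gaussian noise is
#' applied to the in-situ products otherwise. Products sharing one
#' predictor (the OLCI Turbid TSM/CDOM pair) are driven by a single
#' sampled value, keeping both consistent. Satellite dates fall within
#' +/- 1 day of the in-situ date.
#'
#' @param n number of match-up records (>= 1).
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param registry an `owt_registry` with `sample` intervals.
#' @param noise_sd relative standard deviation of in-situ product noise.
#' @param seed optional integer seed (global RNG state restored).
#' @param kd_model Kd490 model used both to place bands and (later) to
#'   retrieve.
#' @return list with `insitu` (station, date, lake, chl, tsm, cdom400,
#'   cdom412, cdom442, sd), `satellite` (station, date, owt, bands,
#'   fields), and `truth` (character vector of drawn OWT labels).
#' @export
generate_matchups <- function(n, sensor = c("MSI", "OLCI"),
                              registry = builtin_registry(), noise_sd = 0.1,
                              seed = NULL, kd_model = kd490_model()) {
  sensor <- match.arg(sensor)
  if (n < 1) stop("n must be >= 1")
  .with_seed(seed, {
    lakes <- c("Razna", "Lubans", "Burtnieks", "Vortsjarv")
    insitu_rows <- vector("list", n)
    sat_rows <- vector("list", n)
    truth <- character(n)
    base_date <- as.Date("2018-04-15")
    for (i in seq_len(n)) {
      owt <- sample(owt_levels(), 1)
      truth[i] <- owt
      arch <- generate_archetype(owt, jitter = 0.2)
      row <- .observation_row(arch$spectrum, sensor)
      xs <- list(); shared <- list()
      y <- list()
      for (product in .products) {
        spec <- registry_lookup(registry, sensor, product, owt)
        key <- paste(spec$source, spec$predictor)
        if (is.null(shared[[key]])) {
          shared[[key]] <- stats::runif(1, spec$sample[1], spec$sample[2])
        }
        xs[[product]] <- shared[[key]]
        y[[product]] <- as.numeric(eval_response(spec, xs[[product]]))
      }
      row <- .solve_bands(row, sensor, owt, xs, kd_model)
      station <- sprintf("S%02d", 1 + (i - 1) %% 49)
      d_insitu <- base_date + (i - 1) %% 200
      noisy <- function(v) v * (1 + stats::rnorm(1, 0, noise_sd))
      cdom <- noisy(y$cdom400)
      insitu_rows[[i]] <- data.frame(
        station = station, date = as.character(d_insitu),
        lake = lakes[1 + (i - 1) %% 4],
        chl = noisy(y$chl), tsm = noisy(y$tsm),
        cdom400 = cdom, cdom412 = cdom_at(cdom, 412),
        cdom442 = cdom_at(cdom, 442), sd = noisy(y$sd),
        stringsAsFactors = FALSE)
      sat_rows[[i]] <- cbind(
        data.frame(station = station,
                   date = as.character(d_insitu + sample(-1:1, 1)),
                   owt = owt, stringsAsFactors = FALSE),
        as.data.frame(row, check.names = FALSE))
    }
    # align columns: product-field columns appear only for some OWTs
    all_cols <- unique(unlist(lapply(sat_rows, names)))
    sat <- do.call(rbind, lapply(sat_rows, function(r) {
      for (col in setdiff(all_cols, names(r))) r[[col]] <- NA_real_
      r[all_cols]
    }))
    list(insitu = do.call(rbind, insitu_rows), satellite = sat,
         truth = truth)
  })
}

#' Scene specification for the synthetic scene generator
#'
#' @param nx,ny grid size in pixels.
#' @param layout `"quadrants"` (four OWTs in four quadrants) or a
#'   character matrix of OWT labels (`ny` x `nx`) tiling the grid.
#' @param quadrant_owts the four OWTs used by the quadrant layout.
#' @param jitter log-normal sdlog of the per-pixel parameter jitter.
#' @param noise_sd relative sd of additive reflectance noise (0 = none).
#' @param seed integer seed; the same seed reproduces the scene
#'   bit-for-bit.
#' @return list of class `owt_scene_spec`.
#' @export
scene_spec <- function(nx = 16, ny = 16, layout = "quadrants",
                       quadrant_owts = c("Clear", "Turbid", "VeryTurbid",
                                         "Brown"),
                       jitter = 0.1, noise_sd = 0, seed = 1L) {
  if (is.character(layout) && length(layout) == 1L) {
    stopifnot(layout == "quadrants", length(quadrant_owts) == 4L,
              all(quadrant_owts %in% owt_levels()))
    labels <- matrix("", ny, nx)
    labels[seq_len(ceiling(ny / 2)), seq_len(ceiling(nx / 2))] <- quadrant_owts[1]
    labels[seq_len(ceiling(ny / 2)), (ceiling(nx / 2) + 1):nx] <- quadrant_owts[2]
    labels[(ceiling(ny / 2) + 1):ny, seq_len(ceiling(nx / 2))] <- quadrant_owts[3]
    labels[(ceiling(ny / 2) + 1):ny, (ceiling(nx / 2) + 1):nx] <- quadrant_owts[4]
  } else {
    labels <- layout
    stopifnot(is.matrix(labels), all(dim(labels) == c(ny, nx)),
              all(labels %in% owt_levels()))
  }
  structure(list(nx = nx, ny = ny, labels = labels, jitter = jitter,
                 noise_sd = noise_sd, seed = seed),
            class = "owt_scene_spec")
}

#' Generate a synthetic labelled scene of per-band reflectances
#'
#' Every pixel draws a bio-optical archetype of its region's OWT (with
#' parameter jitter), runs the forward model and resamples to the sensor's
#' bands. Identical seeds give bit-identical output.
#'
#' @param spec an [scene_spec()].
#' @param sensor `"MSI"` or `"OLCI"`.
#' @param coeffs forward-model coefficients.
#' @return list with `stack` (array `[ny, nx, band]`, band names on the
#'   third dimension, water-leaving reflectance) and `labels` (the truth
#'   label matrix).
#' @export
generate_scene <- function(spec, sensor = c("MSI", "OLCI"),
                           coeffs = bio_optical_coeffs()) {
  sensor <- match.arg(sensor)
  stopifnot(inherits(spec, "owt_scene_spec"))
  bands <- band_set(sensor)
  bn <- band_names(bands)
  .with_seed(spec$seed, {
    stack <- array(NA_real_, dim = c(spec$ny, spec$nx, length(bn)),
                   dimnames = list(NULL, NULL, bn))
    for (i in seq_len(spec$ny)) {
      for (j in seq_len(spec$nx)) {
        arch <- generate_archetype(spec$labels[i, j], jitter = spec$jitter,
                                   coeffs = coeffs)
        pb <- resample_to_bands(arch$spectrum, bands)
        v <- pb$values
        if (spec$noise_sd > 0) {
          v <- v + stats::rnorm(length(v), 0, spec$noise_sd * mean(v))
        }
        stack[i, j, ] <- v
      }
    }
    list(stack = stack, labels = spec$labels)
  })
}
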