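test_that("predictor expressions evaluate by plain arithmetic", {
  row <- obs_row(TOA_R705 = 0.02, TOA_R665 = 0.01, TOA_R740 = 0.015,
                 TOA_R709 = 0.010, TOA_R754 = 0.006)
  expect_equal(eval_predictor("R705/R665", row, "TOA", "MSI"), 2.0)
  # ratio difference vanishes when all bands are equal
  eq <- obs_row(TOA_R740 = 0.02, TOA_R705 = 0.02, TOA_R665 = 0.02)
  expect_equal(eval_predictor("R740/R705 - R740/R665", eq, "TOA", "MSI"), 0)
  # peak-height expression, hand arithmetic: 0.010 - (0.008 + 0.006)/2
  pk <- obs_row(TOA_R709 = 0.010, TOA_R665 = 0.008, TOA_R754 = 0.006)
  expect_equal(eval_predictor("R709 - (R665 + R754)/2", pk, "TOA", "OLCI"),
               0.003)
})

test_that("missing predictor inputs propagate as missing, never zero", {
  row <- obs_row(TOA_R705 = 0.02)
  expect_true(is.na(eval_predictor("R705/R665", row, "TOA", "MSI")))
  expect_true(is.na(eval_predictor("conc_tsm", row, "C2RCC", "MSI")))
  # division by zero flags a diagnostic
  z <- obs_row(TOA_R705 = 0.02, TOA_R665 = 0)
  out <- eval_predictor("R705/R665", z, "TOA", "MSI")
  expect_true(is.na(out))
  expect_match(attr(out, "diagnostic"), "non-finite")
})

test_that("response forms evaluate their closed forms", {
  reg <- builtin_registry()
  brown <- registry_lookup(reg, "MSI", "chl", "Brown")
  expect_equal(eval_response(brown, 1.0), 30.1)   # 293.5 - 263.4
  expect_equal(eval_response(brown, 2.0), 323.6)  # 293.5*2 - 263.4
  expect_equal(eval_response("power", 1.0, coef = c(1.6941, -0.677)), 1.6941)
  expect_equal(eval_response("exponential", 0, coef = c(9.4, -0.67)), 9.4)
  # power form rejects non-positive input
  expect_true(is.na(eval_response("power", -1, coef = c(1, -1))))
  expect_true(is.na(eval_response("power", 0, coef = c(1, -1))))
})

test_that("inputs outside the calibrated domain are missing with diagnostic", {
  e <- registry_lookup(builtin_registry(), "MSI", "cdom400", "Brown")
  y <- eval_response(e, c(1.5, 99))
  expect_false(is.na(y[1]))
  expect_true(is.na(y[2]))
  expect_match(attr(y, "diagnostic"), "domain")
})

test_that("the Kd490 -> KdPAR -> Secchi chain has the printed anchors", {
  expect_equal(kd_par(0), 0.3291)
  expect_equal(kd_par(1), 0.4349 + 0.3291)
  expect_equal(secchi_from_kdpar(1), 1.6941)
  kd <- seq(0.1, 5, length.out = 60)
  kp <- kd_par(kd)
  expect_true(all(diff(kp) > 0))
  expect_true(all(diff(secchi_from_kdpar(kp)) < 0))
  expect_true(all(kp > 0) && all(secchi_from_kdpar(kp) > 0))
})

test_that("kd490 binds the sensor's red band and degrades gracefully", {
  row <- obs_row(TOA_R490 = 0.03, TOA_R560 = 0.04, TOA_R705 = 0.02,
                 TOA_R709 = 0.05)
  m <- kd490_model()
  kd_msi <- kd490(row, "MSI", "TOA", m)
  kd_olci <- kd490(row, "OLCI", "TOA", m)
  expect_equal(kd_msi, kd490_from_bands(0.03, 0.04, 0.02, m))
  expect_equal(kd_olci, kd490_from_bands(0.03, 0.04, 0.05, m))
  expect_gt(kd_olci, kd_msi)  # monotone in the red band
  # degenerate config: zero ratio exponents give a constant
  flat <- kd490_model(a0 = 0.2, a1 = 0, a2 = 0)
  expect_equal(kd490(row, "MSI", "TOA", flat), 10^0.2)
  # increasing the red band never decreases kd490
  kds <- vapply(seq(0.005, 0.08, length.out = 30), function(r) {
    kd490_from_bands(0.03, 0.04, r, m)
  }, numeric(1))
  expect_true(all(diff(kds) > 0))
  # non-positive reflectance is flagged missing
  bad <- kd490_from_bands(-0.01, 0.04, 0.02, m)
  expect_true(is.na(bad))
  expect_match(attr(bad, "diagnostic"), "non-positive")
})

test_that("retrieve applies the per-OWT registry formulas", {
  row <- obs_row(TOA_R705 = 0.02, TOA_R665 = 0.01)
  out <- retrieve(row, "Brown", "MSI")
  expect_equal(out$chl, 323.6)  # ratio 2 through the Brown chl model
  prov <- attr(out, "provenance")
  expect_match(prov$chl$formula, "R705/R665")
  # products with missing inputs stay missing, others are computed
  expect_true(is.na(out$tsm))   # no C2X_R705 on this row

  mod <- obs_row(TOA_R665 = 0.02, TOA_R705 = 0.02, C2RCC_conc_tsm = 10,
                 TOA_R490 = 0.03, C2X_Kd_489 = 2.0)
  out2 <- retrieve(mod, "Moderate", "MSI")
  expect_equal(out2$tsm, -0.91 * 10 + 39.29)
  expect_equal(out2$sd, -0.18 * 2 + 1.44)
  # same row without the processor field: tsm missing, sd still computed
  mod$C2RCC_conc_tsm <- NULL
  out3 <- retrieve(mod, "Moderate", "MSI")
  expect_true(is.na(out3$tsm))
  expect_equal(out3$sd, out2$sd)
})

test_that("Unclassified observations yield all-missing products with reason", {
  out <- retrieve(obs_row(TOA_R705 = 0.02), "Unclassified", "MSI")
  expect_true(all(is.na(unlist(out))))
  expect_match(attr(out, "provenance")$reason, "Unclassified")
})

test_that("scene retrieval equals pixel-wise scalar retrieval", {
  set.seed(31)
  sc <- generate_scene(scene_spec(nx = 4, ny = 3, layout = matrix(
    sample(owt_levels(), 12, replace = TRUE), 3, 4), jitter = 0.1,
    seed = 9L), "MSI")
  # water-leaving stack doubles for every source in this equivalence check
  stacks <- list(TOA = sc$stack, C2RCC = sc$stack, C2X = sc$stack)
  grids <- retrieve_scene(stacks, sc$labels, "MSI")
  bn <- dimnames(sc$stack)[[3]]
  for (i in 1:3) for (j in 1:4) {
    row <- list()
    for (src in names(stacks)) row[paste0(src, "_", bn)] <- sc$stack[i, j, ]
    ref <- retrieve(as.data.frame(row, check.names = FALSE),
                    sc$labels[i, j], "MSI")
    for (p in c("chl", "tsm", "cdom400", "sd")) {
      expect_equal(grids[[p]][i, j], ref[[p]])
    }
  }
})

test_that("uniform scenes give constant products; Unclassified gives none", {
  sc <- generate_scene(scene_spec(nx = 3, ny = 3, layout = matrix(
    "Turbid", 3, 3), jitter = 0, seed = 2L), "MSI")
  stacks <- list(TOA = sc$stack, C2RCC = sc$stack, C2X = sc$stack)
  grids <- retrieve_scene(stacks, sc$labels, "MSI")
  for (p in c("chl", "tsm", "cdom400", "sd")) {
    vals <- grids[[p]][!is.na(grids[[p]])]
    if (length(vals) > 1) expect_lt(diff(range(vals)), 1e-12)
  }
  un <- matrix("Unclassified", 3, 3)
  grids2 <- retrieve_scene(stacks, un, "MSI")
  for (p in c("chl", "tsm", "cdom400", "sd")) {
    expect_true(all(is.na(grids2[[p]])))
  }
})

test_that("CDOM spectral-slope conversion is exponential in wavelength", {
  expect_equal(cdom_at(5, 400), 5)
  expect_equal(cdom_at(5, 412, slope = 0.018), 5 * exp(-0.018 * 12))
  expect_lt(cdom_at(5, 442), cdom_at(5, 412))
})
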