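test_that("spectral correlation similarity matches hand-computed cases", {
  r <- c(0.01, 0.03, 0.02, 0.05)
  expect_equal(spectral_correlation_similarity(r, r), 1)
  expect_equal(spectral_correlation_similarity(-r + 0.1, r), 0)
  # Pearson rho of (1,2,3) and (1,3,2) is 0.5 -> score 0.75
  expect_equal(spectral_correlation_similarity(c(1, 2, 3), c(1, 3, 2)), 0.75)
  deg <- spectral_correlation_similarity(c(1, 1, 1), r[1:3])
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("modified spectral angle similarity matches hand-computed cases", {
  r <- c(0.02, 0.01, 0.04)
  expect_equal(modified_spectral_angle_similarity(3.7 * r, r), 1)
  expect_equal(modified_spectral_angle_similarity(c(1, 0), c(0, 1)), 0)
  # 45 degrees between (1,0) and (1,1) -> 0.5
  expect_equal(modified_spectral_angle_similarity(c(1, 0), c(1, 1)), 0.5)
  expect_equal(modified_spectral_angle_similarity(5 * r, 0.1 * r), 1)
  deg <- modified_spectral_angle_similarity(c(0, 0), c(1, 1))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("both similarity measures stay within [0, 1] on random vectors", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(3:14, 1)
    x <- random_band_vector(n)
    r <- random_band_vector(n)
    scs <- as.numeric(spectral_correlation_similarity(x, r))
    msas <- as.numeric(modified_spectral_angle_similarity(x, r))
    expect_gte(scs, 0); expect_lte(scs, 1)
    expect_gte(msas, 0); expect_lte(msas, 1)
  }
})

test_that("each shipped reference classifies as itself with positive margin", {
  for (sensor in c("MSI", "OLCI")) {
    lib <- default_reference_library(sensor)
    for (owt in owt_levels()) {
      res <- classify(lib$references[[owt]], lib)
      expect_identical(res$label, owt)
      expect_gt(res$margin, 0)
      expect_equal(res$best_score, 1, tolerance = 1e-7)
    }
  }
})

test_that("classification is invariant to positive scaling of the input", {
  lib <- default_reference_library("MSI")
  set.seed(5)
  for (k in 1:10) {
    arch <- generate_archetype(sample(owt_levels(), 1), jitter = 0.2)
    x <- resample_to_bands(arch$spectrum, band_set("MSI"))
    base <- classify(x, lib)
    for (sc in c(0.1, 0.5, 7)) {
      scaled <- stats::setNames(x$values * sc, x$band_names)
      res <- classify(scaled, lib)
      expect_identical(res$label, base$label)
      expect_equal(res$scores$combined, base$scores$combined, tolerance = 1e-9)
    }
  }
})

test_that("scaled reference still classifies to its own class", {
  lib <- default_reference_library("MSI")
  half <- lib$references$Turbid * 0.5
  expect_identical(classify(half, lib)$label, "Turbid")
})

test_that("degenerate spectra are Unclassified with a flag", {
  lib <- default_reference_library("MSI")
  zero <- stats::setNames(rep(0, length(lib$band_subset)), lib$band_subset)
  res <- classify(zero, lib)
  expect_identical(res$label, "Unclassified")
  expect_true(res$degenerate)
  withna <- stats::setNames(c(NA, rep(0.02, length(lib$band_subset) - 1)),
                            lib$band_subset)
  expect_identical(classify(withna, lib)$label, "Unclassified")
})

test_that("missing bands are reported by name", {
  lib <- default_reference_library("MSI")
  x <- stats::setNames(rep(0.02, 3), c("R443", "R490", "R560"))
  expect_error(classify(x, lib), "R665")
})

test_that("classify agrees with an independent brute-force evaluation", {
  lib <- default_reference_library("OLCI")
  set.seed(23)
  for (k in 1:25) {
    x <- stats::setNames(random_band_vector(length(lib$band_subset)),
                         lib$band_subset)
    res <- classify(x, lib, threshold = 0)
    oracle <- vapply(owt_levels(), function(owt) {
      brute_force_combined(as.numeric(x),
                           as.numeric(lib$references[[owt]][lib$band_subset]))
    }, numeric(1))
    expect_equal(res$scores$combined, as.numeric(oracle), tolerance = 1e-12)
    expect_identical(res$label, names(which.max(oracle)))
  }
})

test_that("classify_scene labels pixels and passes missing pixels through", {
  lib <- default_reference_library("MSI")
  bn <- lib$band_subset
  stack <- array(NA_real_, c(2, 2, length(bn)), dimnames = list(NULL, NULL, bn))
  truth <- matrix(c("Clear", "Brown", "Turbid", "Clear"), 2, 2)
  for (i in 1:2) for (j in 1:2) stack[i, j, ] <- lib$references[[truth[i, j]]]
  out <- classify_scene(stack, lib)
  expect_identical(out$labels, truth)
  # knock out one pixel entirely
  stack[1, 2, ] <- NA_real_
  out2 <- classify_scene(stack, lib)
  expect_identical(out2$labels[1, 2], "Unclassified")
  expect_identical(out2$labels[2, ], truth[2, ])
})

test_that("classifier recovers labels on a seeded synthetic scene", {
  sc <- generate_scene(scene_spec(nx = 16, ny = 16, seed = 1L), "MSI")
  cl <- classify_scene(sc$stack, default_reference_library("MSI"))
  expect_gte(mean(cl$labels == sc$labels), 0.9)
})

test_that("OWT error magnitude follows the distant-pair table", {
  expect_identical(owt_error_magnitude("Clear", "Brown"), "large")
  expect_identical(owt_error_magnitude("Clear", "Turbid"), "large")
  expect_identical(owt_error_magnitude("Clear", "VeryTurbid"), "large")
  expect_identical(owt_error_magnitude("Turbid", "Brown"), "large")
  expect_identical(owt_error_magnitude("Turbid", "VeryTurbid"), "little")
  expect_identical(owt_error_magnitude("Clear", "Moderate"), "little")
  expect_identical(owt_error_magnitude("Moderate", "Brown"), "little")
  expect_identical(owt_error_magnitude("Moderate", "Moderate"), "correct")
  expect_identical(owt_error_magnitude("Clear", "Unclassified"), "unclassified")
})

test_that("error magnitude is symmetric for the large/little decision", {
  lv <- owt_levels()
  for (a in lv) for (b in lv) {
    expect_identical(owt_error_magnitude(a, b), owt_error_magnitude(b, a))
  }
})
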