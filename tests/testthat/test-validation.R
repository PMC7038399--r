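test_that("r_squared matches the literal definition including negatives", {
  y <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # hand evaluation: 1 - 11 / (96/9)
  expect_equal(r_squared(c(0, 0, 4), c(1, 1, 1)), -0.03125)
  deg <- r_squared(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
})

test_that("r_squared is invariant under joint affine transforms", {
  set.seed(13)
  y <- stats::rnorm(20, 10, 3)
  yhat <- y + stats::rnorm(20, 0, 1)
  base <- r_squared(y, yhat)
  for (k in 1:5) {
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1, 0, 10)
    expect_equal(r_squared(a * y + b, a * yhat + b), base, tolerance = 1e-10)
  }
})

test_that("rmse matches hand-computed values and scaling laws", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(2, 5), 3)
  set.seed(17)
  y <- stats::rnorm(15); yhat <- stats::rnorm(15)
  base <- rmse(y, yhat)
  expect_equal(rmse(y + 3.3, yhat + 3.3), base)   # translation invariant
  expect_equal(rmse(2.5 * y, 2.5 * yhat), 2.5 * base)  # scales linearly
})

test_that("owt accuracy and its error distribution sum to 100", {
  lv <- owt_levels()
  res <- owt_accuracy(lv, lv)
  expect_equal(res$accuracy, 100)
  expect_equal(unname(res$distribution["correct"]), 100)

  res2 <- owt_accuracy(rep("Clear", 4), rep("Brown", 4))
  expect_equal(res2$accuracy, 0)
  expect_equal(unname(res2$distribution["large"]), 100)

  truth <- c("Clear", "Brown", "Moderate", "Turbid")
  derived <- c("Clear", "Brown", "Turbid", "Moderate")
  res3 <- owt_accuracy(truth, derived)
  expect_equal(res3$accuracy, 50)
  expect_equal(unname(res3$distribution["little"]), 50)

  set.seed(29)
  for (k in 1:20) {
    t <- sample(lv, 12, replace = TRUE)
    d <- sample(c(lv, "Unclassified"), 12, replace = TRUE)
    expect_equal(sum(owt_accuracy(t, d)$distribution), 100)
  }
  expect_error(owt_accuracy(character(0), character(0)), "empty")
})

test_that("match-ups pair stations within the one-day window", {
  insitu <- data.frame(station = "S01", date = "2018-07-10", chl = 12)
  sat <- data.frame(station = "S01",
                    date = c("2018-07-09", "2018-07-11", "2018-07-12"),
                    TOA_R705 = c(0.02, 0.03, 0.04))
  mu <- build_matchups(insitu, sat, "MSI")
  expect_equal(nrow(mu), 2L)  # D-1 and D+1 kept, D+2 excluded
  expect_setequal(mu$time_delta, c(-1, 1))
  expect_true(all(mu$window == "3x3"))
  expect_true(all(build_matchups(insitu, sat, "OLCI")$window == "single"))
})

test_that("duplicate satellite rows and missing stations are handled", {
  insitu <- data.frame(station = "S01", date = "2018-07-10", chl = 12)
  sat <- data.frame(station = c("S01", "S01"),
                    date = c("2018-07-10", "2018-07-10"),
                    TOA_R705 = c(0.02, 0.02))
  expect_warning(mu <- build_matchups(insitu, sat, "MSI"), "duplicate")
  expect_equal(nrow(mu), 1L)
  other <- data.frame(station = "S99", date = "2018-07-10", TOA_R705 = 0.02)
  expect_warning(empty <- build_matchups(insitu, other, "MSI"), "common")
  expect_equal(nrow(empty), 0L)
})

test_that("summaries report per group and pooled; tiny groups are flagged", {
  m <- data.frame(insitu_chl = c(10, 20, 30, 40),
                  derived_chl = c(11, 19, 31, 39),
                  owt = c("Brown", "Brown", "Turbid", "Clear"),
                  lake = c("A", "A", "B", "B"))
  pooled <- summarize_matchups(m, "chl", "pooled")
  expect_equal(nrow(pooled), 2L)  # the single group equals the pooled row
  expect_equal(pooled$r2[1], pooled$r2[2])
  expect_equal(pooled$rmse[1], pooled$rmse[2])

  perfect <- summarize_matchups(
    data.frame(insitu_chl = c(10, 20, 30, 40), derived_chl = c(10, 20, 30, 40),
               lake = c("A", "A", "B", "B")), "chl", "by_lake")
  expect_true(all(perfect$r2 == 1))
  expect_true(all(perfect$rmse == 0))

  byowt <- summarize_matchups(m, "chl", "by_owt")
  expect_true(byowt$flagged[byowt$group == "Clear"])
  expect_true(is.na(byowt$r2[byowt$group == "Clear"]))
  expect_false(byowt$flagged[byowt$group == "pooled"])

  bins <- summarize_matchups(m, "chl", "by_insitu_bins")
  expect_true(all(c("low", "medium", "high") %in% bins$group))
})

test_that("missing pairs are dropped and counted", {
  m <- data.frame(insitu_chl = c(10, 20, NA), derived_chl = c(11, NA, 30))
  s <- summarize_matchups(m, "chl", "pooled")
  expect_equal(attr(s, "n_dropped"), 2L)
  expect_equal(s$n[s$group == "pooled"], 1L)
})

test_that("synthetic match-up validation improves monotonically as noise falls", {
  sigmas <- c(0.2, 0.05, 0)
  rmses <- vapply(sigmas, function(sg) {
    gm <- generate_matchups(120, "MSI", noise_sd = sg, seed = 101)
    mu <- retrieve_table(build_matchups(gm$insitu, gm$satellite, "MSI"),
                         "owt", "MSI")
    rmse(mu$insitu_chl, mu$derived_chl) / sqrt(mean(mu$derived_chl^2))
  }, numeric(1))
  expect_true(all(diff(rmses) < 0))
  expect_lt(rmses[3], 1e-10)
})

test_that("pooled rmse recovers the injected relative noise level", {
  gm <- generate_matchups(500, "OLCI", noise_sd = 0.1, seed = 55)
  mu <- retrieve_table(build_matchups(gm$insitu, gm$satellite, "OLCI"),
                       "owt", "OLCI")
  for (p in c("chl", "tsm", "cdom400", "sd")) {
    y <- mu[[paste0("insitu_", p)]]
    yh <- mu[[paste0("derived_", p)]]
    rel <- rmse(y, yh) / sqrt(mean(yh^2))
    expect_gt(rel, 0.08)
    expect_lt(rel, 0.12)
  }
})
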