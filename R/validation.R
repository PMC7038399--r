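#' Coefficient of determination
#'
#' Literal implementation of
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' with observed in-situ values `y` and model-predicted values `yhat`.
#' Not clamped: worse-than-mean predictions give negative values. A
#' constant observed vector has an undefined total sum of squares and
#' returns `NA` with attribute `degenerate = TRUE`.
#'
#' @param y observed values, length >= 2.
#' @param yhat predicted values, same length.
#' @return scalar score, at most 1.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) return(structure(NA_real_, degenerate = TRUE))
  1 - sum((y - yhat)^2) / sstot
}

#' Root mean squared error
#'
#' `RMSE = sqrt(sum((y - yhat)^2) / n)`, in the product's units.
#'
#' @param y,yhat observed and predicted values of equal length >= 1.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  sqrt(mean((y - yhat)^2))
}

#' OWT classification accuracy and error-magnitude distribution
#'
#' Accuracy is the percentage of cases where the derived OWT equals the
#' reference OWT. The distribution additionally splits the errors by
#' [owt_error_magnitude()] into little differences (neighbouring classes),
#' large differences (distant class pairs) and unclassified cases; the four
#' percentages sum to 100 exactly.
#'
#' @param truth,derived character vectors of OWT labels, equal length >= 1.
#' @return list with `accuracy` (percent), `n`, and `distribution`
#'   (named numeric: percent correct/little/large/unclassified).
#' @export
owt_accuracy <- function(truth, derived) {
  stopifnot(length(truth) == length(derived))
  n <- length(truth)
  if (n == 0L) stop("empty label vectors")
  mag <- owt_error_magnitude(truth, derived)
  counts <- vapply(c("correct", "little", "large", "unclassified"),
                   function(k) sum(mag == k), numeric(1))
  list(accuracy = 100 * counts[["correct"]] / n, n = n,
       distribution = 100 * counts / n)
}

#' Pair in-situ samples with satellite observations
#'
#' Joins the two tables on station id and keeps every pair whose dates lie
#' within the time window (default +/- 1 day, date granularity), so one
#' station sampled on day D can yield up to three match-ups (images on
#' D-1, D, D+1), each contributing independently. Duplicate satellite rows
#' (same station and timestamp) are dropped with a warning. MSI match-up
#' reflectances are expected to be 3x3-pixel window means supplied
#' upstream; OLCI single-pixel values.
#'
#' @param insitu data.frame with `station`, `date` and in-situ product
#'   columns (`chl`, `tsm`, `cdom400`, ..., `sd`).
#' @param satellite data.frame with `station`, `date` and band/field
#'   columns in the observation naming convention.
#' @param sensor `"MSI"` or `"OLCI"` (records the pixel window used).
#' @param max_lag_days half-width of the pairing window in days.
#' @return data.frame of match-ups: station, both dates, `time_delta`
#'   (days, satellite minus in-situ), `window`, in-situ columns prefixed
#'   `insitu_`, satellite columns unprefixed.
#' @export
build_matchups <- function(insitu, satellite, sensor = c("MSI", "OLCI"),
                           max_lag_days = 1) {
  sensor <- match.arg(sensor)
  stopifnot(all(c("station", "date") %in% names(insitu)),
            all(c("station", "date") %in% names(satellite)))
  dup <- duplicated(satellite[, c("station", "date")])
  if (any(dup)) {
    warning(sum(dup), " duplicate satellite row(s) for the same station and date dropped")
    satellite <- satellite[!dup, , drop = FALSE]
  }
  common <- intersect(insitu$station, satellite$station)
  if (length(common) == 0L) {
    warning("no common stations between the in-situ and satellite tables")
    return(data.frame())
  }
  window <- if (sensor == "MSI") "3x3" else "single"
  out <- list()
  for (i in seq_len(nrow(insitu))) {
    cand <- satellite[satellite$station == insitu$station[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    lag <- as.numeric(as.Date(cand$date) - as.Date(insitu$date[i]))
    cand <- cand[abs(lag) <= max_lag_days, , drop = FALSE]
    lag <- lag[abs(lag) <= max_lag_days]
    if (nrow(cand) == 0L) next
    ins <- insitu[i, , drop = FALSE]
    names(ins) <- paste0("insitu_", names(ins))
    for (k in seq_len(nrow(cand))) {
      out[[length(out) + 1L]] <- cbind(
        ins, cand[k, , drop = FALSE],
        data.frame(time_delta = lag[k], window = window),
        row.names = NULL)
    }
  }
  if (length(out) == 0L) {
    warning("no match-ups within the time window")
    return(data.frame())
  }
  do.call(rbind, out)
}

#' Default low/medium/high bins at the terciles of the in-situ values
#' @param x numeric in-situ values.
#' @return numeric cutpoints (lower, upper) between the three bins.
#' @export
tercile_bins <- function(x) {
  as.numeric(stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE))
}

#' Validation summary: R-squared and RMSE per group
#'
#' Computes n, R-squared and RMSE between in-situ (`insitu_<product>`) and
#' derived (`derived_<product>`) values, pooled over all pairs and within
#' each group of the chosen scheme: by lake, by binned in-situ value
#' (low/medium/high), or by derived OWT. Pairs with a missing value on
#' either side are dropped and counted. Pooled statistics are always
#' computed on the pooled pairs (not averaged over groups). Groups with
#' fewer than 2 pairs are flagged (`flagged = TRUE`) and carry `NA`
#' R-squared.
#'
#' @param matchups data.frame of match-ups carrying both columns.
#' @param product one of `"chl"`, `"tsm"`, `"cdom400"`, `"sd"`.
#' @param grouping `"pooled"`, `"by_lake"` (needs an `insitu_lake` or
#'   `lake` column), `"by_insitu_bins"`, or `"by_owt"` (needs an `owt`
#'   column with the derived labels).
#' @param bins cutpoints for `"by_insitu_bins"`; default terciles of the
#'   in-situ values.
#' @return data.frame with one row per group plus a `"pooled"` row:
#'   `group`, `n`, `r2`, `rmse`, `flagged`; attribute `n_dropped` counts
#'   pairs lost to missing values.
#' @export
summarize_matchups <- function(matchups, product,
                               grouping = c("pooled", "by_lake",
                                            "by_insitu_bins", "by_owt"),
                               bins = NULL) {
  grouping <- match.arg(grouping)
  ycol <- paste0("insitu_", product)
  yhatcol <- paste0("derived_", product)
  stopifnot(ycol %in% names(matchups), yhatcol %in% names(matchups))
  y <- matchups[[ycol]]
  yhat <- matchups[[yhatcol]]
  keep <- !is.na(y) & !is.na(yhat)
  n_dropped <- sum(!keep)
  m <- matchups[keep, , drop = FALSE]
  y <- y[keep]; yhat <- yhat[keep]
  key <- switch(grouping,
    pooled = rep("all", nrow(m)),
    by_lake = {
      lc <- if ("insitu_lake" %in% names(m)) "insitu_lake" else "lake"
      if (!lc %in% names(m)) stop("by_lake grouping needs a lake column")
      as.character(m[[lc]])
    },
    by_insitu_bins = {
      if (is.null(bins)) bins <- tercile_bins(y)
      cut(y, c(-Inf, bins, Inf), labels = c("low", "medium", "high"))
    },
    by_owt = {
      if (!"owt" %in% names(m)) stop("by_owt grouping needs an 'owt' column")
      as.character(m[["owt"]])
    })
  one <- function(yy, yh, label) {
    flagged <- length(yy) < 2L
    data.frame(group = label, n = length(yy),
               r2 = if (flagged) NA_real_ else as.numeric(r_squared(yy, yh)),
               rmse = rmse(yy, yh), flagged = flagged)
  }
  groups <- sort(unique(as.character(key)))
  res <- do.call(rbind, lapply(groups, function(g) {
    sel <- key == g
    one(y[sel], yhat[sel], g)
  }))
  res <- rbind(res, one(y, yhat, "pooled"))
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Write a JSON validation report
#'
#' @param summaries named list of data.frames from [summarize_matchups()]
#'   and/or an [owt_accuracy()] result under the name `owt`.
#' @param path output JSON path.
#' @export
write_validation_report <- function(summaries, path) {
  jsonlite::write_json(summaries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
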