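# shared fixtures built in code at test time

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a smooth positive random spectrum on a wavelength grid
random_spectrum <- function(wl = seq(400, 900, by = 2.5)) {
  base <- 0.02 + 0.01 * sin(wl / 50) + stats::runif(1, 0, 0.01)
  owt_spectrum(wl, base, source = "insitu", sensor = "hyperspectral")
}

# random band vector (possibly with negatives) for property tests
random_band_vector <- function(n, allow_negative = TRUE) {
  v <- stats::rnorm(n, mean = 0.02, sd = 0.02)
  if (!allow_negative) v <- abs(v) + 1e-4
  v
}

# independent re-derivation of the combined similarity, written from the
# definitions (used as a brute-force oracle against classify())
brute_force_combined <- function(x, r) {
  scs <- (stats::cor(x, r) + 1) / 2
  m <- min(c(x, r))
  if (m < 0) { x <- x - m; r <- r - m }
  ct <- sum(x * r) / sqrt(sum(x^2) * sum(r^2))
  msas <- 1 - (2 / pi) * acos(min(1, max(-1, ct)))
  (scs + msas) / 2
}

# a minimal observation row with chosen band values
obs_row <- function(...) {
  as.data.frame(list(...), check.names = FALSE)
}
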