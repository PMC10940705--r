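# Independent oracles and small fixture builders used across the suite.

# Noise-free piecewise-linear reference trace: baseline 100 AU (t < 60 s),
# drop to 90 at 60 s, linear rise to 300 at 120 s, linear decay to 200 at
# 360 s; sampled every 2 s. All breakpoints fall on the grid so trapezoidal
# integration of the samples is exact.
piecewise_trace <- function() {
  t <- seq(0, 360, by = 2)
  f <- ifelse(t < 60, 100,
              ifelse(t <= 120, 90 + (300 - 90) * (t - 60) / 60,
                     300 - 100 * (t - 120) / 240))
  tibble::tibble(plate = "ORACLE", well = "A1", time_s = t, fluorescence = f)
}

# Closed-form expectations for the reference trace:
#   P1 = F0 = 100 (flat pre-injection baseline)
#   P4 = 300 (peak), P2 = 200
#   P3 = (300 - 90) / 60 = 3.5 (rise is a single line, so any least-squares
#        fit inside it recovers the slope exactly)
#   P5 = P6 = (200 - 300) / 240 = -5/12 (single decay line)
#   P7 = integral of (F - 100) from 60 to 360
#      = (-10 + 200)/2 * 60 + (200 + 100)/2 * 240 = 5700 + 36000 = 41700
piecewise_expected <- list(p1 = 100, p2 = 200, p3 = 3.5, p4 = 300,
                           p5 = -5 / 12, p6 = -5 / 12, p7 = 41700)

# Explicit sort-and-interpolate percentile (rank q * (n - 1)), written
# independently of stats::quantile.
quantile_oracle <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- q * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  if (lo + 1 >= n) return(xs[n])
  xs[lo + 1] + frac * (xs[lo + 2] - xs[lo + 1])
}

# Brute-force difference index: pointwise relative difference over the
# combined range, then the percentile oracle.
di_oracle <- function(a, b, q = 0.95) {
  rng <- max(c(a, b)) - min(c(a, b))
  if (rng == 0) return(0)
  quantile_oracle(abs(a - b) / rng, q)
}

# Left-rectangle integral of (f - f0), the brute-force AUC reference.
rect_auc_oracle <- function(t, f, f0) {
  dt <- diff(t)
  sum((f[-length(f)] - f0) * dt)
}

# Small in-memory screen fixture files for I/O tests.
write_trace_fixture <- function(path, text) {
  writeLines(text, path)
  path
}

empty_truth <- function() {
  tibble::tibble(compound_id = character(), kind = character(),
                 magnitude = numeric(), selectivity = character())
}
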