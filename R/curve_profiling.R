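## Seven-parameter kinetic curve profiling.
##
## Per well trace the profiler reports:
##   P1  baseline fluorescence immediately before agonist addition (= F0)
##   P2  maximal Ca2+ increase, P4 - F0
##   P3  slope 1: rise slope from the post-injection trough to the peak
##   P4  peak fluorescence after agonist addition
##   P5  slope 2: post-peak decline (0 when absent)
##   P6  slope 3: late-phase slope from a per-agonist start time
##   P7  area under the baseline-subtracted curve (trapezoid, signed)
##
## All response parameters use F - F0, not F/F0: the baseline drifts upward
## before injection (dye leakage) and subtracting the terminal pre-injection
## level is robust to that.

#' Profiling configuration
#'
#' @param slope3_start_s Named per-agonist start times (s from recording
#'   start) for the late-phase slope; defaults CRP 650 s, thrombin 500 s.
#' @param baseline_window_samples Number of terminal pre-injection samples
#'   whose median defines P1 = F0.
#' @param smoothing_window_samples Moving-average width (odd) used only to
#'   locate the peak region.
#' @param slope2_absent_frac Slope 2 is reported as exactly 0 when the
#'   baseline-subtracted signal never falls below this fraction of the
#'   baseline-subtracted peak inside the slope-2 window.
#' @param slope3_min_tail_s Fallback: when the configured slope-3 start would
#'   leave fewer than 5 trailing sample intervals, the start is moved to
#'   (trace end - this many seconds).
#' @param injection_auto Auto-detect the injection drop near the configured
#'   time instead of trusting it exactly.
#' @param injection_search_s Half-width (s) of the auto-detection window.
#' @return A `profiling_config` list.
#' @export
profiling_config <- function(slope3_start_s = c(CRP = 650, thrombin = 500),
                             baseline_window_samples = 5,
                             smoothing_window_samples = 3,
                             slope2_absent_frac = 0.97,
                             slope3_min_tail_s = 60,
                             injection_auto = FALSE,
                             injection_search_s = 10) {
  if (smoothing_window_samples %% 2 != 1 || smoothing_window_samples < 1) {
    cs_abort("smoothing_window_samples must be a positive odd integer",
             "parameter_error")
  }
  if (baseline_window_samples < 1) {
    cs_abort("baseline_window_samples must be >= 1", "parameter_error")
  }
  if (slope2_absent_frac <= 0 || slope2_absent_frac > 1) {
    cs_abort("slope2_absent_frac must be in (0, 1]", "parameter_error")
  }
  structure(list(slope3_start_s = slope3_start_s,
                 baseline_window_samples = as.integer(baseline_window_samples),
                 smoothing_window_samples = as.integer(smoothing_window_samples),
                 slope2_absent_frac = slope2_absent_frac,
                 slope3_min_tail_s = slope3_min_tail_s,
                 injection_auto = injection_auto,
                 injection_search_s = injection_search_s),
            class = "profiling_config")
}

## least-squares slope of y on x (closed form, no lm() overhead)
ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sum(dx * (y - my)) / sum(dx * dx)
}

## centered moving average with shrinking edge windows, O(n)
roll_mean_center <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the injection sample
#'
#' Injection of agonist (a relatively large volume, with the tip briefly in
#' the light path) produces a sharp drop in fluorescence. By default the
#' configured layout time is trusted and the index of the first sample at or
#' after it is returned; in auto mode the largest single-step negative
#' deflection within `injection_search_s` of the configured time is used,
#' falling back (with `low_confidence = TRUE`) when no convincing drop
#' exists.
#'
#' @param trace One-well trace tibble (or any list with `time_s`,
#'   `fluorescence`).
#' @param injection_time_s Configured injection time (s); must lie inside
#'   the trace time span.
#' @param config A [profiling_config()].
#' @return List with `index` (1-based sample index) and `low_confidence`.
#' @export
locate_injection <- function(trace, injection_time_s,
                             config = profiling_config()) {
  t <- trace$time_s
  f <- trace$fluorescence
  if (injection_time_s < t[1] || injection_time_s > t[length(t)]) {
    cs_abort(sprintf("injection time %g s outside trace span [%g, %g]",
                     injection_time_s, t[1], t[length(t)]), "parameter_error")
  }
  configured <- which(t >= injection_time_s)[1]
  if (!config$injection_auto) {
    return(list(index = configured, low_confidence = FALSE))
  }
  steps <- diff(f)
  cand <- which(abs(t[-1] - injection_time_s) <= config$injection_search_s)
  cand <- cand[cand >= 1]
  if (length(cand) == 0) return(list(index = configured, low_confidence = TRUE))
  k <- cand[which.min(steps[cand])]
  scale <- stats::mad(steps, constant = 1.4826)
  convincing <- steps[k] < 0 && (scale == 0 || steps[k] < -5 * scale)
  if (!convincing) return(list(index = configured, low_confidence = TRUE))
  list(index = k + 1L, low_confidence = FALSE)
}

#' Baseline (P1 / F0) from the terminal pre-injection window
#'
#' P1 is the median of the last `baseline_window_samples` samples before the
#' injection sample; because of dye-leakage drift only this terminal window
#' — the level "immediately before agonist addition" — is representative.
#'
#' @inheritParams locate_injection
#' @param injection_index 1-based injection sample index.
#' @return List with `p1_baseline_au` and `f0_au` (equal by definition).
#' @export
compute_baseline <- function(trace, injection_index,
                             config = profiling_config()) {
  w <- config$baseline_window_samples
  if (injection_index - 1L < w) {
    cs_abort(sprintf("need >= %d pre-injection samples for the baseline, have %d",
                     w, injection_index - 1L), "profiling_error")
  }
  p1 <- median(trace$fluorescence[(injection_index - w):(injection_index - 1L)])
  list(p1_baseline_au = p1, f0_au = p1)
}

## Numeric profiling core; returns a named numeric vector. Kept free of
## tibble construction so whole plates profile quickly.
profile_vec <- function(t, f, injection_index, agonist, config) {
  n <- length(t)
  inj <- injection_index
  dt <- (t[n] - t[1]) / (n - 1)
  w <- config$baseline_window_samples
  p1 <- median(f[(inj - w):(inj - 1L)])
  f0 <- p1

  post <- (inj + 1L):n
  sm <- roll_mean_center(f, config$smoothing_window_samples)
  half <- (config$smoothing_window_samples - 1L) %/% 2L
  # Peak location: earliest post-injection sample whose smoothed value is
  # within a noise-scaled tolerance of the smoothed maximum (tolerance 0 for
  # noise-free traces). Taking the raw argmax instead would let the peak
  # wander over flat-topped sustained responses and distort the Z-score
  # tails of P2/P4 across a plate. P4 is the raw maximum within half a
  # smoothing window of that location.
  sigma_hat <- mad(diff(f)) / sqrt(2)
  delta <- 3 * sigma_hat / sqrt(config$smoothing_window_samples)
  sm_max <- max(sm[post])
  i_sm <- post[sm[post] >= sm_max - delta][1]
  lo <- max(inj + 1L, i_sm - half)
  hi <- min(n, i_sm + half)
  peak <- (lo:hi)[which.max(f[lo:hi])]
  p4 <- f[peak]
  p2 <- p4 - f0

  # slope 1: fitted over the 10-90% portion of the rise, located on the
  # smoothed trace between the post-injection trough and the peak. Window
  # endpoints selected on raw extrema would jitter by single samples from
  # well to well and turn the slope into a discrete mixture; amplitude-
  # fraction crossings keep every window sample on the rise itself.
  seg <- inj:max(i_sm, inj + 1L)
  m_s <- min(sm[seg])
  amp <- sm[seg[length(seg)]] - m_s
  p3 <- 0
  if (amp > 0) {
    lo3 <- seg[sm[seg] >= m_s + 0.10 * amp][1]
    hi3 <- seg[sm[seg] >= m_s + 0.90 * amp][1]
    if (!is.na(lo3) && !is.na(hi3) && hi3 - lo3 >= 1L) {
      p3 <- ls_slope(t[lo3:hi3], f[lo3:hi3])
    } else {
      trough <- seg[max(which(f[seg] == min(f[seg])))]
      if (peak > trough) p3 <- ls_slope(t[trough:peak], f[trough:peak])
    }
  }

  # slope 3 start: configured per-agonist time, clamped into the trace
  s3_cfg <- unname(config$slope3_start_s[[agonist]])
  s3 <- if (s3_cfg <= t[n] - 5 * dt) s3_cfg else t[n] - config$slope3_min_tail_s
  s3 <- min(max(s3, t[peak]), t[n] - dt)
  idx6 <- which(t >= s3)[1]

  # slope 2 over [peak, slope-3 start); exactly 0 when no decline: the
  # baseline-subtracted signal never dips below slope2_absent_frac of P2
  win5 <- if (idx6 - 1L > peak) peak:(idx6 - 1L) else integer(0)
  p5 <- 0
  slope2_absent <- TRUE
  if (length(win5) >= 2L && p2 > 0) {
    declined <- any((f[win5] - f0) < config$slope2_absent_frac * p2)
    if (declined) {
      p5 <- ls_slope(t[win5], f[win5])
      slope2_absent <- FALSE
    }
  }

  p6 <- if (n > idx6) ls_slope(t[idx6:n], f[idx6:n]) else 0

  # signed trapezoidal AUC of (F - F0) from injection to trace end
  y <- f[inj:n] - f0
  tt <- t[inj:n]
  p7 <- sum(diff(tt) * (y[-length(y)] + y[-1]) / 2)

  c(p1_baseline_au = p1, p2_max_increase_au = p2, p3_slope1_au_s = p3,
    p4_peak_au = p4, p5_slope2_au_s = p5, p6_slope3_au_s = p6,
    p7_auc_au_s = p7, f0_au = f0, injection_index = inj, peak_index = peak,
    slope2_absent = as.numeric(slope2_absent))
}

#' Extract the seven curve characteristics from one trace
#'
#' @param trace One-well trace tibble sorted by time.
#' @param agonist `"CRP"` or `"thrombin"` (selects the slope-3 start time).
#' @param injection_time_s Injection time (s); used with [locate_injection()]
#'   when `injection_index` is not given.
#' @param injection_index Optional explicit 1-based injection sample index.
#' @param config A [profiling_config()].
#' @return One-row tibble with `p1` ... `p7`, `f0`, `injection_index`,
#'   `peak_index`, `slope2_absent`, `low_confidence_injection` plus the
#'   trace identity columns.
#' @export
profile_trace <- function(trace, agonist, injection_time_s = NULL,
                          injection_index = NULL,
                          config = profiling_config()) {
  t <- trace$time_s
  f <- trace$fluorescence
  if (length(t) < 10L) cs_abort("trace has fewer than 10 samples", "profiling_error")
  if (is.unsorted(t, strictly = TRUE)) {
    cs_abort("trace time must be strictly increasing", "profiling_error")
  }
  low_conf <- FALSE
  if (is.null(injection_index)) {
    if (is.null(injection_time_s)) {
      cs_abort("either injection_time_s or injection_index is required",
               "parameter_error")
    }
    li <- locate_injection(trace, injection_time_s, config)
    injection_index <- li$index
    low_conf <- li$low_confidence
  }
  if (injection_index - 1L < config$baseline_window_samples) {
    cs_abort(sprintf("need >= %d pre-injection samples for the baseline, have %d",
                     config$baseline_window_samples, injection_index - 1L),
             "profiling_error")
  }
  if (injection_index >= length(t)) {
    cs_abort("trace does not extend past the injection", "profiling_error")
  }
  v <- profile_vec(t, f, injection_index, agonist, config)
  tibble::tibble(
    plate = trace$plate[1] %||% NA_character_,
    well = trace$well[1] %||% NA_character_,
    agonist = agonist,
    p1 = v[["p1_baseline_au"]], p2 = v[["p2_max_increase_au"]],
    p3 = v[["p3_slope1_au_s"]], p4 = v[["p4_peak_au"]],
    p5 = v[["p5_slope2_au_s"]], p6 = v[["p6_slope3_au_s"]],
    p7 = v[["p7_auc_au_s"]], f0 = v[["f0_au"]],
    injection_index = as.integer(v[["injection_index"]]),
    peak_index = as.integer(v[["peak_index"]]),
    slope2_absent = v[["slope2_absent"]] == 1,
    low_confidence_injection = low_conf)
}

#' Profile every well of a plate
#'
#' All wells of a plate share one time grid and injection time; the profiler
#' exploits that to stay fast at 1536-well scale.
#'
#' @param traces Long trace tibble for one plate.
#' @param layout The plate's [plate_layout()].
#' @param config A [profiling_config()].
#' @return Tidy tibble, one row per well, with the [profile_trace()] columns
#'   plus the well `role` and `compound_id`.
#' @export
profile_plate <- function(traces, layout, config = profiling_config()) {
  agonist <- layout$agonist
  plate_id <- layout$plate_id
  traces <- traces[traces$plate == plate_id, ]
  if (nrow(traces) == 0) {
    cs_abort(sprintf("no traces for plate %s", plate_id), "data_error")
  }
  wells <- split(seq_len(nrow(traces)), traces$well)
  out <- matrix(NA_real_, nrow = length(wells), ncol = 11L)
  lowconf <- logical(length(wells))
  well_names <- names(wells)
  for (i in seq_along(wells)) {
    idx <- wells[[i]]
    t <- traces$time_s[idx]
    f <- traces$fluorescence[idx]
    if (is.unsorted(t)) {
      o <- order(t)
      t <- t[o]; f <- f[o]
    }
    li <- locate_injection(list(time_s = t, fluorescence = f),
                           layout$injection_time_s, config)
    lowconf[i] <- li$low_confidence
    out[i, ] <- profile_vec(t, f, li$index, agonist, config)
  }
  res <- tibble::tibble(
    plate = plate_id, well = well_names, agonist = agonist,
    p1 = out[, 1], p2 = out[, 2], p3 = out[, 3], p4 = out[, 4],
    p5 = out[, 5], p6 = out[, 6], p7 = out[, 7], f0 = out[, 8],
    injection_index = as.integer(out[, 9]), peak_index = as.integer(out[, 10]),
    slope2_absent = out[, 11] == 1, low_confidence_injection = lowconf)
  dplyr::left_join(res, layout$wells[c("well", "role", "compound_id")],
                   by = "well")
}
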