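## Duplicate-reproducibility (difference index) QC and automated artifact
## detection.
##
## The difference index (DI) scores how well the A and B duplicate traces of
## a compound agree: pointwise |A - B| divided by the combined range of both
## signals, summarized as its 95th percentile. Pairs with DI above the
## threshold (default 30%) are inconsistent and excluded from Z-scoring.

#' QC configuration
#'
#' @param di_percentile Percentile of the pointwise relative difference that
#'   defines the DI (default 95, must be in `[50, 100]`).
#' @param di_threshold Consistency threshold on the DI (default 0.30).
#' @param interference_mad_multiplier How many MADs a well's pre-injection
#'   median may sit from the control median before it is called
#'   autofluorescent (above) or quenching (below).
#' @param injection_artifact_min_drop_au Minimum step drop (AU) that counts
#'   as an intact injection artifact.
#' @param di_post_injection_only Restrict the DI to the post-injection
#'   segment (pre-injection dye-leakage drift differences would otherwise
#'   dominate).
#' @param min_timepoints Minimum aligned timepoints for a valid DI.
#' @return A `qc_config` list.
#' @export
qc_config <- function(di_percentile = 95, di_threshold = 0.30,
                      interference_mad_multiplier = 6,
                      injection_artifact_min_drop_au = 25,
                      di_post_injection_only = TRUE, min_timepoints = 10L) {
  if (di_threshold <= 0 || di_threshold >= 1) {
    cs_abort("di_threshold must be in (0, 1)", "parameter_error")
  }
  if (di_percentile < 50 || di_percentile > 100) {
    cs_abort("di_percentile must be in [50, 100]", "parameter_error")
  }
  structure(list(di_percentile = di_percentile, di_threshold = di_threshold,
                 interference_mad_multiplier = interference_mad_multiplier,
                 injection_artifact_min_drop_au = injection_artifact_min_drop_au,
                 di_post_injection_only = di_post_injection_only,
                 min_timepoints = as.integer(min_timepoints)),
            class = "qc_config")
}

#' Difference-index statistic on two aligned signals
#'
#' `r_t = |A_t - B_t| / (max(A,B) - min(A,B))` with the range taken over the
#' values of *both* signals combined, summarized as the `percentile`-th
#' percentile using linear interpolation between order statistics (rank
#' `q * (n - 1)`). Two identical constant signals have zero combined range
#' and DI defined as 0.
#'
#' @param a,b Numeric vectors of equal length.
#' @param percentile Percentile in `[50, 100]`.
#' @return The DI, a fraction in `[0, 1]`.
#' @export
di_statistic <- function(a, b, percentile = 95) {
  if (length(a) != length(b)) {
    cs_abort("signals must have equal length", "qc_error")
  }
  rng <- max(a, b) - min(a, b)
  if (rng == 0) return(0)
  r <- abs(a - b) / rng
  unname(quantile(r, percentile / 100, type = 7, names = FALSE))
}

#' Duplicate-consistency assessment of an A/B trace pair
#'
#' Traces are aligned to a common time grid (the coarser of the two, by
#' linear interpolation, over the overlapping span) and — by default — to the
#' post-injection segment only, then scored with [di_statistic()].
#'
#' @param trace_a,trace_b One-well trace tibbles.
#' @param config A [qc_config()].
#' @param injection_time_s Injection time used to trim the pre-injection
#'   segment when `di_post_injection_only` is set; `NULL` keeps the whole
#'   trace.
#' @return One-row tibble: `di`, `consistent`, `n_timepoints`.
#' @export
difference_index <- function(trace_a, trace_b, config = qc_config(),
                             injection_time_s = NULL) {
  ta <- trace_a$time_s; fa <- trace_a$fluorescence
  tb <- trace_b$time_s; fb <- trace_b$fluorescence
  if (config$di_post_injection_only && !is.null(injection_time_s)) {
    ka <- ta >= injection_time_s
    kb <- tb >= injection_time_s
    ta <- ta[ka]; fa <- fa[ka]
    tb <- tb[kb]; fb <- fb[kb]
  }
  if (identical(ta, tb)) {
    grid <- ta
    a <- fa; b <- fb
  } else {
    lo <- max(min(ta), min(tb))
    hi <- min(max(ta), max(tb))
    grid <- if (length(ta) <= length(tb)) ta else tb
    grid <- grid[grid >= lo & grid <= hi]
    a <- approx(ta, fa, xout = grid)$y
    b <- approx(tb, fb, xout = grid)$y
  }
  if (length(grid) < config$min_timepoints) {
    cs_abort(sprintf("only %d aligned timepoints (>= %d required) for the DI",
                     length(grid), config$min_timepoints), "qc_error")
  }
  di <- di_statistic(a, b, config$di_percentile)
  tibble::tibble(di = di, consistent = di <= config$di_threshold,
                 n_timepoints = length(grid))
}

#' Detect signal-interfering compounds from pre-injection medians
#'
#' A compound whose pre-injection fluorescence median sits more than
#' `k` MADs above the control distribution is autofluorescent; more than
#' `k` MADs below, fluorescence-quenching.
#'
#' @param trace One-well trace tibble.
#' @param injection_index 1-based injection sample index.
#' @param control_pre_median,control_pre_mad Median and MAD of the
#'   pre-injection medians of the plate's control wells (>= 8 wells).
#' @param config A [qc_config()].
#' @return List: `interference` (`"none"`, `"autofluorescent"`,
#'   `"quencher"`), `pre_median_au`, `post_median_au`.
#' @export
detect_interference <- function(trace, injection_index, control_pre_median,
                                control_pre_mad, config = qc_config()) {
  f <- trace$fluorescence
  pre <- median(f[seq_len(injection_index - 1L)])
  post <- median(f[injection_index:length(f)])
  if (control_pre_mad == 0) {
    cs_warn("control pre-injection MAD is zero; using 1% of the control median as floor",
            "qc_warning")
    control_pre_mad <- 0.01 * abs(control_pre_median)
  }
  k <- config$interference_mad_multiplier
  interference <- if (pre > control_pre_median + k * control_pre_mad) {
    "autofluorescent"
  } else if (pre < control_pre_median - k * control_pre_mad) {
    "quencher"
  } else "none"
  list(interference = interference, pre_median_au = pre, post_median_au = post)
}

## Sharpest downward step near the injection: windowed 3-sample mean
## difference, robust to per-sample noise (a raw single-sample diff at 2%
## noise crosses 25 AU far too often).
injection_drop_depth <- function(t, f, injection_index, search_s = 10) {
  n <- length(f)
  cand <- which(abs(t - t[injection_index]) <= search_s)
  cand <- cand[cand >= 4L & cand <= n - 2L]
  if (length(cand) == 0) return(0)
  depth <- vapply(cand, function(i) {
    mean(f[i:(i + 2L)]) - mean(f[(i - 3L):(i - 1L)])
  }, 0)
  min(depth)
}

#' Detect failed agonist injection
#'
#' A well is flagged only when *both* the injection-drop artifact is missing
#' (no windowed step decrease of at least
#' `injection_artifact_min_drop_au` within 10 s of the injection) *and* its
#' maximal increase is below 5% of the control response — so a strong
#' inhibitor with an intact artifact is never flagged.
#'
#' @param trace One-well trace tibble.
#' @param injection_index 1-based injection sample index.
#' @param p2 The well's maximal increase (P2, AU).
#' @param control_p2_median Median P2 of the plate's agonist-control wells.
#' @param config A [qc_config()].
#' @return Logical.
#' @export
detect_injection_failure <- function(trace, injection_index, p2,
                                     control_p2_median, config = qc_config()) {
  depth <- injection_drop_depth(trace$time_s, trace$fluorescence,
                                injection_index)
  artifact_absent <- depth > -config$injection_artifact_min_drop_au
  artifact_absent && (p2 < 0.05 * control_p2_median)
}

## ---------------------------------------------------------------------------
## Pair- and screen-level QC drivers

split_wells <- function(traces) {
  parts <- split(traces[c("time_s", "fluorescence")], traces$well)
  lapply(parts, function(p) {
    if (is.unsorted(p$time_s)) p[order(p$time_s), ] else p
  })
}

#' QC one duplicate plate pair
#'
#' Computes the per-compound difference index plus per-well interference and
#' injection-failure flags; pair-level flags are the OR (interference: the
#' worse) of the two wells.
#'
#' @param pair One element of a `screen_dataset`'s `pairs` list.
#' @param profiles_a,profiles_b [profile_plate()] outputs for the two plates.
#' @param config A [qc_config()].
#' @return Tibble: `compound_id`, `agonist`, `di`, `consistent`,
#'   `interference`, `injection_failure`, `n_timepoints`.
#' @export
qc_plate_pair <- function(pair, profiles_a, profiles_b, config = qc_config()) {
  la <- pair$layout_a
  wa <- split_wells(pair$traces_a)
  wb <- split_wells(pair$traces_b)

  flags_side <- function(profiles, wells, layout) {
    ctrl <- profiles$role %in% c("agonist_control", "buffer_control")
    if (sum(ctrl) < 8) {
      cs_abort(sprintf("plate %s has %d control wells with profiles (>= 8 required)",
                       layout$plate_id, sum(ctrl)), "qc_error")
    }
    ctrl_pre <- vapply(profiles$well[ctrl], function(wl) {
      tr <- wells[[wl]]
      inj <- profiles$injection_index[profiles$well == wl][1]
      median(tr$fluorescence[seq_len(inj - 1L)])
    }, 0)
    ctrl_pre_median <- median(ctrl_pre)
    ctrl_pre_mad <- mad(ctrl_pre)
    ag <- profiles$role == "agonist_control"
    ctrl_p2 <- median(profiles$p2[ag])

    cmp <- which(profiles$role == "compound")
    res <- vector("list", length(cmp))
    for (j in seq_along(cmp)) {
      i <- cmp[j]
      tr <- wells[[profiles$well[i]]]
      inj <- profiles$injection_index[i]
      intf <- detect_interference(tr, inj, ctrl_pre_median, ctrl_pre_mad, config)
      fail <- detect_injection_failure(tr, inj, profiles$p2[i], ctrl_p2, config)
      res[[j]] <- tibble::tibble(
        compound_id = profiles$compound_id[i], well = profiles$well[i],
        interference = intf$interference, injection_failure = fail,
        pre_median_au = intf$pre_median_au, post_median_au = intf$post_median_au)
    }
    dplyr::bind_rows(res)
  }

  fa <- flags_side(profiles_a, wa, pair$layout_a)
  fb <- flags_side(profiles_b, wb, pair$layout_b)

  cmp_wells <- la$wells[la$wells$role == "compound", c("well", "compound_id")]
  out <- vector("list", nrow(cmp_wells))
  for (i in seq_len(nrow(cmp_wells))) {
    wl <- cmp_wells$well[i]
    dia <- difference_index(wa[[wl]], wb[[wl]], config,
                            injection_time_s = la$injection_time_s)
    ia <- fa[fa$well == wl, ]
    ib <- fb[fb$well == wl, ]
    intf <- unique(c(ia$interference, ib$interference))
    intf <- setdiff(intf, "none")
    out[[i]] <- tibble::tibble(
      compound_id = cmp_wells$compound_id[i], agonist = la$agonist,
      di = dia$di, consistent = dia$consistent,
      interference = if (length(intf)) intf[1] else "none",
      injection_failure = any(ia$injection_failure, ib$injection_failure),
      n_timepoints = dia$n_timepoints)
  }
  dplyr::bind_rows(out)
}

#' QC every pair of a screen dataset
#'
#' @param dataset A `screen_dataset`.
#' @param profiles Named list of [profile_plate()] tibbles keyed by plate id
#'   (computed when `NULL`).
#' @param config A [qc_config()].
#' @param profiling_config Passed to [profile_plate()] when profiles are
#'   computed here.
#' @return Tibble with one row per compound x agonist.
#' @export
qc_screen <- function(dataset, profiles = NULL, config = qc_config(),
                      profiling_config = calscreen::profiling_config()) {
  if (is.null(profiles)) profiles <- profile_screen(dataset, profiling_config)
  out <- lapply(dataset$pairs, function(pair) {
    qc_plate_pair(pair, profiles[[pair$layout_a$plate_id]],
                  profiles[[pair$layout_b$plate_id]], config)
  })
  dplyr::bind_rows(out)
}

#' Profile every plate of a screen dataset
#'
#' @param dataset A `screen_dataset`.
#' @param config A [profiling_config()].
#' @return Named list of per-plate profile tibbles keyed by plate id.
#' @export
profile_screen <- function(dataset, config = profiling_config()) {
  profiles <- list()
  for (pair in dataset$pairs) {
    profiles[[pair$layout_a$plate_id]] <-
      profile_plate(pair$traces_a, pair$layout_a, config)
    profiles[[pair$layout_b$plate_id]] <-
      profile_plate(pair$traces_b, pair$layout_b, config)
  }
  profiles
}
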