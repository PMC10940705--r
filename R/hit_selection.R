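## Per-plate normalization, Z-scoring and the agonist-specific hit-selection
## cascade.
##
## Curve parameters are first expressed as percent of the plate's
## agonist-control mean (set at 100%), A/B duplicates are averaged, Z-scores
## are computed per parameter over the compound wells of each plate pair, and
## compounds are then filtered through the cascade:
##   1 DI-consistent  2 active (|Z| > 4)  3 agonist-specific  4 inhibitor
##   5 artifact-free  6 ADME-Tox clean (external flag)

#' Hit-selection configuration
#'
#' @param z_threshold Absolute Z-score above which a parameter counts toward
#'   an "active" call (default 4).
#' @param active_parameters Parameters eligible for the activity call
#'   (default P2-P7; P1 flags interference rather than activity).
#' @param direction_parameters Parameters whose Z sign decides
#'   inhibitor/potentiator (default P2 and P7; must be a subset of
#'   `active_parameters`).
#' @param min_active_params How many active parameters are needed.
#' @param z_method `"robust"` (median/MAD, the default: per-plate SD is
#'   badly inflated by interferers and strong actives) or `"classic"`
#'   (mean/SD).
#' @param min_control_wells Minimum usable agonist-control wells per plate.
#' @param min_compound_wells Minimum compound wells in the Z reference
#'   distribution.
#' @return A `selection_config` list.
#' @export
selection_config <- function(z_threshold = 4,
                             active_parameters = c("p2", "p3", "p4", "p5", "p6", "p7"),
                             direction_parameters = c("p2", "p7"),
                             min_active_params = 1,
                             z_method = c("robust", "classic"),
                             min_control_wells = 8,
                             min_compound_wells = 16) {
  z_method <- match.arg(z_method)
  if (z_threshold <= 0) cs_abort("z_threshold must be > 0", "parameter_error")
  if (!all(direction_parameters %in% active_parameters)) {
    cs_abort("direction_parameters must be a subset of active_parameters",
             "parameter_error")
  }
  if (!all(active_parameters %in% PARAM_COLS)) {
    cs_abort("active_parameters must come from p1..p7", "parameter_error")
  }
  structure(list(z_threshold = z_threshold,
                 active_parameters = active_parameters,
                 direction_parameters = direction_parameters,
                 min_active_params = min_active_params, z_method = z_method,
                 min_control_wells = min_control_wells,
                 min_compound_wells = min_compound_wells),
            class = "selection_config")
}

#' Normalize curve parameters to the plate's agonist-control mean
#'
#' Each parameter is divided by the mean over the plate's agonist-control
#' wells and expressed as a percentage (controls average 100% by
#' construction). A parameter whose control mean is exactly zero has no
#' meaningful percent scale; it is carried as missing and excluded from
#' activity calls.
#'
#' @param profiles [profile_plate()] output for one plate.
#' @param layout The plate's [plate_layout()].
#' @param config A [selection_config()].
#' @return The profile tibble with added `pct_p1` ... `pct_p7` columns.
#' @export
normalize_to_controls <- function(profiles, layout,
                                  config = selection_config()) {
  ctrl <- profiles$role == "agonist_control"
  if (sum(ctrl) < config$min_control_wells) {
    cs_abort(sprintf("plate %s rejected: %d usable agonist-control wells (>= %d required)",
                     layout$plate_id, sum(ctrl), config$min_control_wells),
             "data_error")
  }
  for (p in PARAM_COLS) {
    m <- mean(profiles[[p]][ctrl])
    if (m == 0) {
      cs_warn(sprintf("plate %s: control mean of %s is 0; percent undefined",
                      layout$plate_id, p), "normalization_warning")
      profiles[[paste0("pct_", p)]] <- NA_real_
    } else {
      profiles[[paste0("pct_", p)]] <- profiles[[p]] / m * 100
    }
  }
  profiles
}

#' Per-plate Z-scores of normalized parameters
#'
#' Z is the number of (robust) standard deviations a compound well's
#' normalized parameter lies from the plate's compound-well center; control
#' wells are excluded from the reference distribution. The classical method
#' uses mean and n-1 SD; the robust default uses median and MAD.
#'
#' @param normalized [normalize_to_controls()] output (columns `pct_*`), for
#'   one or more plates (column `plate` groups them).
#' @param config A [selection_config()].
#' @return Input with added `z_p1` ... `z_p7` columns (for every well;
#'   reference distribution is compound wells only).
#' @export
zscore_per_plate <- function(normalized, config = selection_config()) {
  out <- normalized
  for (p in PARAM_COLS) out[[paste0("z_", p)]] <- NA_real_
  for (pl in unique(normalized$plate)) {
    rows <- which(normalized$plate == pl)
    cmp <- rows[normalized$role[rows] == "compound"]
    if (length(cmp) < config$min_compound_wells) {
      cs_abort(sprintf("plate %s: %d compound wells (>= %d required for Z-scoring)",
                       pl, length(cmp), config$min_compound_wells), "data_error")
    }
    for (p in PARAM_COLS) {
      x <- normalized[[paste0("pct_", p)]][cmp]
      if (all(is.na(x))) next
      if (config$z_method == "classic") {
        center <- mean(x, na.rm = TRUE)
        scale <- sd(x, na.rm = TRUE)
      } else {
        center <- median(x, na.rm = TRUE)
        scale <- mad(x, na.rm = TRUE)
        if (is.na(scale) || scale == 0) scale <- sd(x, na.rm = TRUE)
      }
      if (is.na(scale) || scale == 0) {
        cs_warn(sprintf("plate %s: %s has zero spread; all Z set to 0", pl, p),
                "zscore_warning")
        out[[paste0("z_", p)]][rows] <- 0
      } else {
        out[[paste0("z_", p)]][rows] <-
          (normalized[[paste0("pct_", p)]][rows] - center) / scale
      }
    }
  }
  out
}

#' Activity and direction call from a compound's Z-scores
#'
#' A compound is active when at least `min_active_params` of the configured
#' parameters exceed `|Z| > z_threshold`. The direction is `inhibitor` when
#' every direction parameter beyond the threshold is negative, `potentiator`
#' when every one is positive, and `mixed` otherwise (including the
#' indeterminate case where the activity came only from non-direction
#' parameters).
#'
#' @param z Named numeric vector of Z-scores (names `p1` ... `p7`).
#' @param config A [selection_config()].
#' @return List with `active` (logical) and `direction`.
#' @export
call_activity <- function(z, config = selection_config()) {
  za <- z[config$active_parameters]
  n_hit <- sum(abs(za) > config$z_threshold, na.rm = TRUE)
  active <- n_hit >= config$min_active_params
  if (!active) return(list(active = FALSE, direction = "none"))
  zd <- z[config$direction_parameters]
  zd <- zd[!is.na(zd) & abs(zd) > config$z_threshold]
  direction <- if (length(zd) == 0) {
    "mixed"
  } else if (all(zd < 0)) {
    "inhibitor"
  } else if (all(zd > 0)) {
    "potentiator"
  } else "mixed"
  list(active = TRUE, direction = direction)
}

#' log2 effect matrix for heatmapping
#'
#' `log2(percent_of_control / 100)` per compound x parameter; non-positive
#' percentages have no log2 effect and are carried as missing.
#'
#' @param effects Tibble with `compound_id` and `pct_*` columns (e.g. the
#'   averaged pair table in a cascade result).
#' @param parameters Which parameters to include.
#' @return Numeric matrix, rows = compounds, cols = parameters.
#' @export
log2_effect_matrix <- function(effects, parameters = PARAM_COLS) {
  cols <- paste0("pct_", parameters)
  m <- as.matrix(effects[cols])
  m[m <= 0] <- NA
  m <- log2(m / 100)
  rownames(m) <- effects$compound_id
  colnames(m) <- parameters
  m
}

## ---------------------------------------------------------------------------
## The cascade

#' Run the agonist-specific hit-selection cascade
#'
#' Stage order per agonist: (0) screened; (1) DI-consistent duplicates;
#' (2) active, `|Z| > 4` on the averaged A/B normalized parameters;
#' (3) agonist-specific — active for exactly one agonist; (4) inhibitor
#' direction; (5) artifact rejection (interference, injection failure);
#' (6) ADME-Tox flag when annotations are supplied (unknown compounds are
#' retained and logged).
#'
#' @param dataset A `screen_dataset`.
#' @param qc [qc_screen()] output (computed when `NULL`).
#' @param profiles [profile_screen()] output (computed when `NULL`).
#' @param config A [selection_config()].
#' @param profiling_config,qc_config Used when profiles / qc are computed
#'   here.
#' @param annotations Optional annotation tibble (`compound_id`,
#'   `admet_fail`); defaults to the dataset's own annotations.
#' @return List of class `cascade_result`: `verdicts` (one row per compound
#'   x agonist), `report` (a `selection_report`), `effects` (averaged
#'   normalized + Z table) and `qc`.
#' @export
run_cascade <- function(dataset, qc = NULL, profiles = NULL,
                        config = selection_config(),
                        profiling_config = calscreen::profiling_config(),
                        qc_config = calscreen::qc_config(),
                        annotations = NULL) {
  annotations <- annotations %||% dataset$annotations
  if (is.null(profiles)) profiles <- profile_screen(dataset, profiling_config)
  if (is.null(qc)) qc <- qc_screen(dataset, profiles, qc_config)

  # per pair: normalize both sides, average duplicates, Z-score per pair
  effects <- dplyr::bind_rows(lapply(dataset$pairs, function(pair) {
    na <- normalize_to_controls(profiles[[pair$layout_a$plate_id]],
                                pair$layout_a, config)
    nb <- normalize_to_controls(profiles[[pair$layout_b$plate_id]],
                                pair$layout_b, config)
    pct <- paste0("pct_", PARAM_COLS)
    keep <- c("well", "role", "compound_id", pct)
    merged <- dplyr::inner_join(na[keep], nb[keep], by = c("well", "role", "compound_id"),
                                suffix = c("_a", "_b"))
    for (p in pct) {
      merged[[p]] <- (merged[[paste0(p, "_a")]] + merged[[paste0(p, "_b")]]) / 2
    }
    merged$plate <- paste(pair$source_plate, pair$agonist, sep = "_")
    merged$agonist <- pair$agonist
    merged[c("plate", "agonist", "well", "role", "compound_id", pct)]
  }))
  effects <- zscore_per_plate(effects, config)

  # activity calls for compound wells
  cmp <- effects[effects$role == "compound", ]
  zcols <- paste0("z_", PARAM_COLS)
  calls <- lapply(seq_len(nrow(cmp)), function(i) {
    z <- setNames(as.numeric(cmp[i, zcols]), PARAM_COLS)
    call_activity(z, config)
  })
  cmp$active <- vapply(calls, `[[`, TRUE, "active")
  cmp$direction <- vapply(calls, `[[`, "", "direction")

  verdicts <- dplyr::left_join(
    cmp[c("agonist", "compound_id", "well", "active", "direction", zcols,
          paste0("pct_", PARAM_COLS))],
    qc[c("compound_id", "agonist", "di", "consistent", "interference",
         "injection_failure")],
    by = c("compound_id", "agonist"))

  # specificity needs the other agonist's (consistent & active) verdict
  act <- verdicts$consistent & verdicts$active
  key <- paste(verdicts$compound_id, verdicts$agonist)
  other <- paste(verdicts$compound_id,
                 ifelse(verdicts$agonist == "CRP", "thrombin", "CRP"))
  act_by_key <- setNames(act, key)
  other_state <- act_by_key[other]
  measured_other <- !is.na(other_state)
  if (any(!measured_other)) {
    cs_warn(sprintf("%d compound x agonist record(s) lack the other agonist; treated as non-specific",
                    sum(!measured_other)), "specificity_warning")
  }
  verdicts$specific <- act & measured_other & !ifelse(is.na(other_state), TRUE, other_state)
  verdicts$artifact_rejected <- verdicts$interference != "none" |
    verdicts$injection_failure
  both_active <- act & measured_other & other_state
  verdicts$specific_agonist <- dplyr::case_when(
    both_active ~ "both",
    verdicts$specific & verdicts$agonist == "CRP" ~ "CRP_only",
    verdicts$specific & verdicts$agonist == "thrombin" ~ "thrombin_only",
    .default = "none")

  if (!is.null(annotations)) {
    verdicts <- dplyr::left_join(
      verdicts, annotations[c("compound_id", "admet_fail")], by = "compound_id")
    unknown <- sum(is.na(verdicts$admet_fail))
    if (unknown > 0) {
      cs_warn(sprintf("%d verdict(s) without ADME-Tox annotation; retained", unknown),
              "admet_warning")
    }
  } else {
    verdicts$admet_fail <- NA
  }
  verdicts$admet_rejected <- !is.na(verdicts$admet_fail) & verdicts$admet_fail

  # stage lists per agonist
  stages_for <- function(v) {
    s0 <- v$compound_id
    s1 <- v$compound_id[v$consistent]
    s2 <- v$compound_id[v$consistent & v$active]
    s3 <- v$compound_id[v$consistent & v$specific]
    s4 <- v$compound_id[v$consistent & v$specific & v$direction == "inhibitor"]
    pre5 <- v$consistent & v$specific & v$direction == "inhibitor"
    s5 <- v$compound_id[pre5 & !v$artifact_rejected]
    s6 <- v$compound_id[pre5 & !v$artifact_rejected & !v$admet_rejected]
    tibble::tibble(
      stage = c("screened", "di_consistent", "active", "agonist_specific",
                "inhibitor", "artifact_free", "admet_clean"),
      n = c(length(s0), length(s1), length(s2), length(s3), length(s4),
            length(s5), length(s6)),
      ids = list(s0, s1, s2, s3, s4, s5, s6))
  }
  verdicts$final_hit <- verdicts$consistent & verdicts$specific &
    verdicts$direction == "inhibitor" & !verdicts$artifact_rejected &
    !verdicts$admet_rejected

  report <- structure(list(
    agonists = lapply(split(verdicts, verdicts$agonist), stages_for),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_compounds = length(unique(verdicts$compound_id))),
    class = "selection_report")

  structure(list(verdicts = tibble::as_tibble(verdicts), report = report,
                 effects = effects, qc = qc),
            class = "cascade_result")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d compounds, config %s\n", x$n_compounds,
              substr(x$config_hash, 1, 8)))
  for (ag in names(x$agonists)) {
    st <- x$agonists[[ag]]
    cat(sprintf("  %s: %s\n", ag,
                paste(sprintf("%s=%d", st$stage, st$n), collapse = " > ")))
  }
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
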