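## End-to-end orchestration: manifest-driven screen runs and the seeded
## synthetic demo.

#' Run configuration for a full screen analysis
#'
#' @param manifest Path to a `manifest.csv` (see [write_screen()]).
#' @param output_dir Directory for all persisted stage tables.
#' @param annotations Optional path to a compound annotation CSV.
#' @param profiling,qc,selection Stage configurations.
#' @param seed Integer seed (recorded; the analysis itself is
#'   deterministic).
#' @return A `run_config` list; its hash is embedded in every output.
#' @export
run_config <- function(manifest, output_dir, annotations = NULL,
                       profiling = profiling_config(), qc = qc_config(),
                       selection = selection_config(), seed = 1) {
  cfg <- structure(list(manifest = manifest, output_dir = output_dir,
                        annotations = annotations,
                        profiling = unclass(profiling), qc = unclass(qc),
                        selection = unclass(selection), seed = seed),
                   class = "run_config")
  cfg
}

config_hash <- function(config) {
  rlang::hash(list(config$profiling, config$qc, config$selection, config$seed))
}

#' Execute the full screen pipeline from a manifest
#'
#' read -> profile -> QC -> normalize/Z -> cascade; every stage table is
#' persisted to `output_dir` (`profiles.csv`, `qc.csv`, `effects.csv`,
#' `verdicts.csv`, `report.json`). Each CSV carries a constant `config_hash`
#' column and the JSON report embeds the config snapshot, so outputs of
#' different configurations cannot be silently mixed (see
#' [check_same_run()]).
#'
#' @param config A [run_config()].
#' @return The `cascade_result`, invisibly; side effect: files on disk.
#' @export
run_screen <- function(config) {
  dataset <- read_screen(config$manifest)
  annotations <- if (!is.null(config$annotations)) {
    read_annotations(config$annotations)
  } else dataset$annotations

  prof_cfg <- do.call(profiling_config, config$profiling)
  qc_cfg <- do.call(qc_config, config$qc)
  sel_cfg <- do.call(selection_config, config$selection)

  profiles <- profile_screen(dataset, prof_cfg)
  qc <- qc_screen(dataset, profiles, qc_cfg)
  result <- run_cascade(dataset, qc = qc, profiles = profiles,
                        config = sel_cfg, annotations = annotations)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- function(x) {
    x$config_hash <- hash
    x
  }
  readr::write_csv(stamp(dplyr::bind_rows(profiles)),
                   file.path(config$output_dir, "profiles.csv"), progress = FALSE)
  readr::write_csv(stamp(qc), file.path(config$output_dir, "qc.csv"),
                   progress = FALSE)
  readr::write_csv(stamp(result$effects),
                   file.path(config$output_dir, "effects.csv"), progress = FALSE)
  readr::write_csv(stamp(result$verdicts),
                   file.path(config$output_dir, "verdicts.csv"), progress = FALSE)

  report_json <- list(
    config_hash = hash,
    config = list(profiling = config$profiling, qc = config$qc,
                  selection = config$selection, seed = config$seed),
    stages = lapply(result$report$agonists, function(st) {
      lapply(seq_len(nrow(st)), function(i) {
        list(stage = st$stage[i], n = st$n[i], ids = st$ids[[i]])
      })
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report_json,
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

#' Verify that persisted stage tables come from one configuration
#'
#' @param dir A [run_screen()] output directory.
#' @return `TRUE` invisibly; aborts when hashes disagree.
#' @export
check_same_run <- function(dir) {
  csvs <- c("profiles.csv", "qc.csv", "effects.csv", "verdicts.csv")
  hashes <- vapply(csvs, function(f) {
    tab <- readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                           progress = FALSE, n_max = 1)
    as.character(tab$config_hash[1])
  }, "")
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  hashes <- c(hashes, report = rep$config_hash)
  if (length(unique(hashes)) != 1) {
    cs_abort(sprintf("outputs in %s mix configurations: %s", dir,
                     paste(unique(hashes), collapse = " vs ")), "data_error")
  }
  invisible(TRUE)
}

#' Seeded end-to-end demonstration on synthetic data
#'
#' Generates a synthetic duplicate two-agonist screen with planted effects,
#' runs the full hit-selection cascade, tabulates recovery of the planted
#' agonist-specific inhibitors (confusion table), and confirms up to
#' `max_fits` final hits with seeded synthetic dose-response series and 4PL
#' IC50 fits.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_compounds Compounds in the synthetic screen.
#' @param noise_sd_au Trace noise SD (AU).
#' @param max_fits Dose-response confirmations to run.
#' @param quiet Suppress printing.
#' @return List: `report`, `confusion` (per-agonist tibble), `fits`,
#'   `truth`, `verdicts`.
#' @export
run_end_to_end_demo <- function(seed = 1, n_compounds = 100, noise_sd_au = 8,
                                max_fits = 3, quiet = FALSE) {
  sim <- generate_screen(n_compounds, seed = seed, noise_sd_au = noise_sd_au)
  result <- run_cascade(sim$dataset)

  planted_for <- function(ag) {
    sel <- if (ag == "CRP") "CRP_only" else "thrombin_only"
    sim$truth$compound_id[sim$truth$kind == "inhibitor" &
                            sim$truth$selectivity == sel]
  }
  confusion <- dplyr::bind_rows(lapply(AGONISTS, function(ag) {
    hits <- result$verdicts$compound_id[result$verdicts$agonist == ag &
                                          result$verdicts$final_hit]
    planted <- planted_for(ag)
    all_ids <- sim$truth$compound_id
    tp <- length(intersect(hits, planted))
    fp <- length(setdiff(hits, planted))
    fn <- length(setdiff(planted, hits))
    tn <- length(all_ids) - tp - fp - fn
    tibble::tibble(agonist = ag, tp = tp, fp = fp, fn = fn, tn = tn,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = tn / (tn + fp))
  }))

  hits <- result$verdicts[result$verdicts$final_hit, ]
  fits <- list()
  if (nrow(hits) > 0) {
    hits <- head(hits[order(hits$compound_id), ], max_fits)
    conc <- c(1, 3, 10, 30, 100, 300)
    for (i in seq_len(nrow(hits))) {
      series <- generate_dose_response(
        ic50_um = 30, hill = 1, bottom_pct = 0, top_pct = 100,
        concentrations_um = conc, noise_sd_pct = 5, n_replicates = 3,
        seed = well_seed(seed, "demo-dr", hits$compound_id[i]),
        compound_id = hits$compound_id[i], agonist = hits$agonist[i])
      fits[[i]] <- list(compound_id = hits$compound_id[i],
                        agonist = hits$agonist[i], fit = fit_4pl(series))
    }
  }

  if (!quiet) {
    print(result$report)
    cat("\nPlanted agonist-specific inhibitor recovery:\n")
    print(as.data.frame(confusion), row.names = FALSE)
    for (f in fits) {
      cat(sprintf("%s (%s): ", f$compound_id, f$agonist))
      print(f$fit)
    }
  }
  invisible(list(report = result$report, confusion = confusion, fits = fits,
                 truth = sim$truth, verdicts = result$verdicts))
}
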