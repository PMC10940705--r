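## Synthetic plate-screen generator with known ground truth.
##
## Traces are phenomenological piecewise curves emulating Calcium-6 kinetics:
## a slowly drifting baseline (dye leakage), a sharp fluorescence drop at
## agonist injection (volume addition + tip shadow), a short receptor latency,
## a linear rise to peak, then either a transient decay (thrombin-like, 5 min
## recordings) or a sustained slowly declining plateau (CRP-like, 10 min
## recordings). No receptor kinetics or store-release ODEs are modelled.

#' Kinetic trace template
#'
#' @param agonist `"CRP"` or `"thrombin"`.
#' @param baseline_au Resting fluorescence (AU).
#' @param injection_drop_au Size of the injection artifact drop (AU).
#' @param rise_rate_au_s Initial rise slope (AU/s).
#' @param peak_au Absolute peak fluorescence (AU); must be >= baseline.
#' @param decay_rate_au_s Post-peak decay rate (AU/s, thrombin-like
#'   transient); ignored for CRP templates.
#' @param plateau_slope_au_s Post-peak plateau slope (AU/s, CRP-like
#'   sustained response; usually slightly negative); ignored for thrombin.
#' @param duration_s Total recording length (s). Must cover the injection
#'   plus the post-injection window (600 s for CRP, 300 s for thrombin).
#' @param sample_interval_s Sampling interval (s).
#' @param leakage_slope_au_s Pre-injection baseline drift from dye leakage
#'   (AU/s).
#' @param response_latency_s Delay between injection and the start of the
#'   Ca2+ rise (s).
#' @return A `trace_template` list.
#' @export
trace_template <- function(agonist, baseline_au = 100, injection_drop_au = 40,
                           rise_rate_au_s = 4, peak_au = 500,
                           decay_rate_au_s = 1.2, plateau_slope_au_s = -0.3,
                           duration_s = 660, sample_interval_s = 2,
                           leakage_slope_au_s = 0.05, response_latency_s = 4) {
  if (!agonist %in% AGONISTS) {
    cs_abort(sprintf("unknown agonist '%s'", agonist), "parameter_error")
  }
  if (peak_au < baseline_au) {
    cs_abort("peak_au must be >= baseline_au", "parameter_error")
  }
  if (sample_interval_s <= 0 || duration_s <= 0) {
    cs_abort("duration_s and sample_interval_s must be positive", "parameter_error")
  }
  structure(list(agonist = agonist, baseline_au = baseline_au,
                 injection_drop_au = injection_drop_au,
                 rise_rate_au_s = rise_rate_au_s, peak_au = peak_au,
                 decay_rate_au_s = decay_rate_au_s,
                 plateau_slope_au_s = plateau_slope_au_s,
                 duration_s = duration_s, sample_interval_s = sample_interval_s,
                 leakage_slope_au_s = leakage_slope_au_s,
                 response_latency_s = response_latency_s),
            class = "trace_template")
}

#' Default CRP-like (sustained) template: 660 s recording, injection at 60 s
#' leaves the standard 600 s post-injection window.
#' @export
#' @rdname trace_template
crp_template <- function() {
  trace_template("CRP", rise_rate_au_s = 4, plateau_slope_au_s = -0.3,
                 duration_s = 660)
}

#' Default thrombin-like (transient) template: 360 s recording, fast rise,
#' pronounced decay back toward baseline.
#' @export
#' @rdname trace_template
thrombin_template <- function() {
  trace_template("thrombin", rise_rate_au_s = 13, decay_rate_au_s = 1.2,
                 duration_s = 360)
}

default_templates <- function() {
  list(CRP = crp_template(), thrombin = thrombin_template())
}

#' Planted compound effect
#'
#' @param compound_id Compound identifier.
#' @param kind One of `none`, `inhibitor`, `potentiator`, `autofluorescent`,
#'   `quencher`, `injection_failure`.
#' @param magnitude Response multiplier for inhibitor (< 1) / potentiator
#'   (> 1); whole-trace multiplier for autofluorescent / quencher; must be 1
#'   for `none`.
#' @param agonist_selectivity `CRP_only`, `thrombin_only` or `both`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(compound_id, kind = "none", magnitude = 1,
                           agonist_selectivity = "both") {
  if (!kind %in% EFFECT_KINDS) {
    cs_abort(sprintf("unknown effect kind '%s'", kind), "parameter_error")
  }
  if (!agonist_selectivity %in% SELECTIVITIES) {
    cs_abort(sprintf("unknown agonist_selectivity '%s'", agonist_selectivity),
             "parameter_error")
  }
  if (kind == "none" && magnitude != 1) {
    cs_abort("kind 'none' requires magnitude 1", "parameter_error")
  }
  if (kind == "inhibitor" && magnitude >= 1) {
    cs_abort("inhibitor magnitude must be < 1", "parameter_error")
  }
  if (kind == "potentiator" && magnitude <= 1) {
    cs_abort("potentiator magnitude must be > 1", "parameter_error")
  }
  if (magnitude < 0) cs_abort("magnitude must be >= 0", "parameter_error")
  structure(list(compound_id = compound_id, kind = kind, magnitude = magnitude,
                 agonist_selectivity = agonist_selectivity),
            class = "planted_effect")
}

effect_applies <- function(effect, agonist) {
  effect$kind != "none" &&
    (effect$agonist_selectivity == "both" ||
       (effect$agonist_selectivity == "CRP_only" && agonist == "CRP") ||
       (effect$agonist_selectivity == "thrombin_only" && agonist == "thrombin"))
}

## Deterministic effect-free curve on a time grid. `agonist_response = FALSE`
## reproduces a buffer-control well: injection artifact, no Ca2+ rise.
template_curve <- function(template, injection_time_s, agonist_response = TRUE) {
  tp <- template
  t <- seq(0, tp$duration_s, by = tp$sample_interval_s)
  if (injection_time_s <= 0 || injection_time_s >= tp$duration_s) {
    cs_abort("injection time must fall inside the recording", "parameter_error")
  }
  base <- tp$baseline_au + tp$leakage_slope_au_s * pmin(t, injection_time_s)
  base_inj <- tp$baseline_au + tp$leakage_slope_au_s * injection_time_s
  floor_au <- base_inj - tp$injection_drop_au
  r_peak <- tp$peak_au - floor_au
  rise_t0 <- injection_time_s + tp$response_latency_s
  rise_dur <- r_peak / tp$rise_rate_au_s
  t_peak <- rise_t0 + rise_dur

  r <- numeric(length(t))
  if (agonist_response) {
    rising <- t >= rise_t0 & t < t_peak
    r[rising] <- tp$rise_rate_au_s * (t[rising] - rise_t0)
    after <- t >= t_peak
    if (tp$agonist == "thrombin") {
      r[after] <- pmax(r_peak - tp$decay_rate_au_s * (t[after] - t_peak), 0)
    } else {
      r[after] <- pmax(r_peak + tp$plateau_slope_au_s * (t[after] - t_peak), 0)
    }
  }
  f <- ifelse(t < injection_time_s, base, floor_au + r)
  list(time_s = t, base = base, f = f)
}

#' Generate one synthetic well trace
#'
#' The deterministic curve is baseline(+drift) -> injection drop -> latency
#' -> linear rise -> peak -> decay/plateau, transformed by the planted
#' effect, plus i.i.d. Gaussian noise. With the same seed the trace is
#' bit-identical.
#'
#' @param template A [trace_template()].
#' @param effect A [planted_effect()] or `NULL` (no effect).
#' @param injection_time_s Injection time (s from recording start).
#' @param noise_sd_au Gaussian noise SD (AU); must be >= 0.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param plate_id,well_id Identity columns of the returned trace.
#' @param agonist_response Set `FALSE` for buffer-control wells (vehicle
#'   injection: drop artifact but no response).
#' @return Long trace tibble (`plate`, `well`, `time_s`, `fluorescence`).
#' @export
generate_trace <- function(template, effect = NULL, injection_time_s = 60,
                           noise_sd_au = 0, seed = NULL, plate_id = "SIM",
                           well_id = "A1", agonist_response = TRUE) {
  if (noise_sd_au < 0) cs_abort("noise SD must be >= 0", "parameter_error")
  f <- synth_fluorescence(template, effect, injection_time_s, agonist_response)
  if (noise_sd_au > 0) {
    noise <- if (is.null(seed)) {
      rnorm(length(f$f), 0, noise_sd_au)
    } else {
      withr::with_seed(as.integer(seed), rnorm(length(f$f), 0, noise_sd_au))
    }
    f$f <- f$f + noise
  }
  tibble::tibble(plate = plate_id, well = well_id, time_s = f$time_s,
                 fluorescence = f$f)
}

synth_fluorescence <- function(template, effect, injection_time_s,
                               agonist_response = TRUE) {
  cv <- template_curve(template, injection_time_s, agonist_response)
  f <- cv$f
  if (!is.null(effect) && effect_applies(effect, template$agonist)) {
    switch(effect$kind,
      inhibitor = ,
      potentiator = {
        # scale the whole post-injection deviation from the (drift-frozen)
        # baseline path, so peak-minus-baseline scales exactly by magnitude
        f <- cv$base + effect$magnitude * (f - cv$base)
      },
      autofluorescent = ,
      quencher = {
        f <- effect$magnitude * f
      },
      injection_failure = {
        # no drop artifact, flat post-injection signal
        f <- cv$base
      }
    )
  }
  list(time_s = cv$time_s, f = f)
}

## Deterministic per-well RNG substream: reproducible regardless of the
## order in which wells are generated. Kept < 2^31.
well_seed <- function(seed, plate_id, well_id) {
  chars <- utf8ToInt(paste(plate_id, well_id, sep = "/"))
  h <- 0
  for (c in chars) h <- (h * 131 + c) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

## ---------------------------------------------------------------------------
## Whole-screen generation

#' Default planted-effect mixture
#'
#' Fractions of the compound set assigned to each effect class. Inhibitors
#' carry a 0.2 response multiplier (80% inhibition), potentiators 1.5x,
#' autofluorescent compounds scale the signal 5x, quenchers 0.2x. One
#' quencher class is CRP-only, emulating duration-dependent dye interference
#' that only manifests in the longer CRP recordings; injection failures are
#' per-agonist, emulating plate-run-specific injector faults. The remainder
#' of the compounds are inert.
#'
#' @return Tibble with columns `kind`, `selectivity`, `magnitude`, `fraction`.
#' @export
default_effect_spec <- function() {
  tibble::tribble(
    ~kind,               ~selectivity,    ~magnitude, ~fraction,
    "inhibitor",         "CRP_only",      0.2,        0.05,
    "inhibitor",         "thrombin_only", 0.2,        0.05,
    "inhibitor",         "both",          0.2,        0.02,
    "potentiator",       "both",          1.5,        0.02,
    "autofluorescent",   "both",          5,          0.02,
    "quencher",          "both",          0.2,        0.01,
    "quencher",          "CRP_only",      0.2,        0.01,
    "injection_failure", "CRP_only",      1,          0.01,
    "injection_failure", "thrombin_only", 1,          0.01
  )
}

#' Build the standard screening layout for one plate
#'
#' 1536-well plates follow the standard screening arrangement: 64 buffer
#' controls (columns 1-2), 192 agonist controls (columns 3-8) and up to 1280
#' compound wells (columns 9-48, row-major).
#'
#' @param compound_ids Compounds to place (max 1280).
#' @param plate_id,agonist,duplicate_tag,injection_time_s Plate metadata.
#' @param source_plate Shared compound-plate id.
#' @return A [plate_layout()].
#' @export
screen_layout <- function(compound_ids, plate_id, agonist, duplicate_tag,
                          injection_time_s = 60, source_plate = NULL) {
  n <- length(compound_ids)
  if (n > 1280) cs_abort("at most 1280 compounds per 1536-well plate", "parameter_error")
  ids <- well_ids("well1536")
  col_of <- as.integer(sub("^[A-Z]+", "", ids))
  buffer <- ids[col_of <= 2]
  agctrl <- ids[col_of >= 3 & col_of <= 8]
  cmp <- ids[col_of >= 9][seq_len(n)]
  wells <- tibble::tibble(
    well = c(buffer, agctrl, cmp),
    role = c(rep("buffer_control", length(buffer)),
             rep("agonist_control", length(agctrl)),
             rep("compound", n)),
    compound_id = c(rep(NA_character_, length(buffer) + length(agctrl)),
                    compound_ids),
    concentration_um = c(rep(NA_real_, length(buffer) + length(agctrl)),
                         rep(10, n)))
  plate_layout(plate_id, "well1536", agonist, duplicate_tag, injection_time_s,
               wells, source_plate = source_plate)
}

#' Generate traces for one laid-out plate
#'
#' @param layout A [plate_layout()].
#' @param template The agonist's [trace_template()].
#' @param truth Ground-truth tibble (`compound_id`, `kind`, `magnitude`,
#'   `selectivity`); compounds absent from it are treated as inert.
#' @param noise_sd_au Per-sample Gaussian noise SD (AU).
#' @param seed Global integer seed; per-well substreams are derived from
#'   (plate, well) so generation order is irrelevant.
#' @return Long trace tibble for every well in the layout.
#' @export
generate_plate <- function(layout, template, truth, noise_sd_au, seed) {
  if (noise_sd_au < 0) cs_abort("noise SD must be >= 0", "parameter_error")
  inj <- layout$injection_time_s
  # deterministic curves, one per distinct effect signature
  base_curves <- new.env(parent = emptyenv())
  det_for <- function(role, compound_id) {
    if (role == "buffer_control") {
      key <- "buffer"
      eff <- NULL
      resp <- FALSE
    } else {
      resp <- TRUE
      if (role == "agonist_control" || is.na(compound_id)) {
        key <- "control"
        eff <- NULL
      } else {
        row <- truth[truth$compound_id == compound_id, ]
        if (nrow(row) == 0 || row$kind[1] == "none") {
          key <- "control"
          eff <- NULL
        } else {
          key <- paste(row$kind[1], row$magnitude[1], row$selectivity[1])
          eff <- planted_effect(compound_id, row$kind[1], row$magnitude[1],
                                row$selectivity[1])
        }
      }
    }
    if (is.null(base_curves[[key]])) {
      base_curves[[key]] <- synth_fluorescence(template, eff, inj, resp)$f
    }
    base_curves[[key]]
  }

  tgrid <- template_curve(template, inj)$time_s
  nt <- length(tgrid)
  wells <- layout$wells
  nw <- nrow(wells)
  fmat <- matrix(0, nrow = nt, ncol = nw)
  for (i in seq_len(nw)) {
    det <- det_for(wells$role[i], wells$compound_id[i])
    if (noise_sd_au > 0) {
      ws <- well_seed(seed, layout$plate_id, wells$well[i])
      det <- det + withr::with_seed(ws, rnorm(nt, 0, noise_sd_au))
    }
    fmat[, i] <- det
  }
  tibble::tibble(
    plate = layout$plate_id,
    well = rep(wells$well, each = nt),
    time_s = rep(tgrid, times = nw),
    fluorescence = as.vector(fmat))
}

#' Generate a duplicate two-agonist synthetic screen with ground truth
#'
#' Produces A/B duplicate plate pairs for both agonists with shared compound
#' placement (emulating one compound source plate used four times), control
#' wells, planted compound effects drawn from `effect_spec`, and independent
#' replicate noise. Compounds beyond 1280 spill onto additional plate pairs.
#'
#' @param n_compounds Number of compounds.
#' @param effect_spec Effect-class mixture (see [default_effect_spec()]);
#'   fractions must sum to <= 1, the remainder being inert compounds.
#' @param templates Named list of per-agonist [trace_template()]s.
#' @param noise_sd_au Gaussian noise SD in AU (default 8 AU, i.e. ~2% of the
#'   control maximal increase of the default templates).
#' @param injection_time_s Injection time for all plates.
#' @param seed Integer seed controlling effect assignment and all well noise.
#' @return List with `dataset` (a `screen_dataset`) and `truth` (tibble
#'   `compound_id`, `kind`, `magnitude`, `selectivity`, covering every
#'   compound).
#' @export
generate_screen <- function(n_compounds, effect_spec = default_effect_spec(),
                            templates = default_templates(), noise_sd_au = 8,
                            injection_time_s = 60, seed = 1) {
  if (n_compounds < 1) cs_abort("n_compounds must be >= 1", "parameter_error")
  if (!is.null(effect_spec) && nrow(effect_spec) > 0) {
    if (sum(effect_spec$fraction) > 1 + 1e-12) {
      cs_abort("effect fractions sum to more than 1", "parameter_error")
    }
  }
  compound_ids <- sprintf("CMP%05d", seq_len(n_compounds))
  truth <- assign_effects(compound_ids, effect_spec, seed)

  n_pairs <- ceiling(n_compounds / 1280)
  plates <- list()
  for (k in seq_len(n_pairs)) {
    idx <- ((k - 1) * 1280 + 1):min(k * 1280, n_compounds)
    src <- sprintf("SRC%02d", k)
    for (ag in AGONISTS) {
      for (tag in c("A", "B")) {
        layout <- screen_layout(
          compound_ids[idx],
          plate_id = sprintf("%s_%s_%s", src, ag, tag),
          agonist = ag, duplicate_tag = tag,
          injection_time_s = injection_time_s, source_plate = src)
        traces <- generate_plate(layout, templates[[ag]], truth, noise_sd_au,
                                 seed)
        plates[[length(plates) + 1L]] <- list(layout = layout, traces = traces)
      }
    }
  }
  list(dataset = pair_plates(plates), truth = truth)
}

assign_effects <- function(compound_ids, effect_spec, seed) {
  n <- length(compound_ids)
  truth <- tibble::tibble(compound_id = compound_ids, kind = "none",
                          magnitude = 1, selectivity = "both")
  if (is.null(effect_spec) || nrow(effect_spec) == 0) return(truth)
  counts <- round(effect_spec$fraction * n)
  if (sum(counts) > n) {
    cs_abort("effect fractions sum to more than 1", "parameter_error")
  }
  order <- withr::with_seed(as.integer(seed), sample.int(n))
  pos <- 0
  for (j in seq_len(nrow(effect_spec))) {
    if (counts[j] == 0) next
    take <- order[(pos + 1):(pos + counts[j])]
    truth$kind[take] <- effect_spec$kind[j]
    truth$magnitude[take] <- effect_spec$magnitude[j]
    truth$selectivity[take] <- effect_spec$selectivity[j]
    pos <- pos + counts[j]
  }
  truth
}

#' Simulate a dose-response series from the four-parameter logistic
#'
#' Responses follow `bottom + (top - bottom) / (1 + (c / ic50)^hill)` (percent
#' of vehicle control) plus Gaussian noise in percent points.
#'
#' @param ic50_um True IC50 (uM), > 0.
#' @param hill Hill coefficient.
#' @param bottom_pct,top_pct Lower/upper plateaus (% of control).
#' @param concentrations_um Concentrations to sample (uM, positive).
#' @param noise_sd_pct Gaussian noise SD in percent points.
#' @param n_replicates Replicates per concentration.
#' @param seed Optional seed.
#' @param compound_id,agonist Identity columns.
#' @return Tibble `compound_id`, `agonist`, `concentration_um`, `response_pct`.
#' @export
generate_dose_response <- function(ic50_um, hill = 1, bottom_pct = 0,
                                   top_pct = 100, concentrations_um,
                                   noise_sd_pct = 0, n_replicates = 1,
                                   seed = NULL, compound_id = "CMP",
                                   agonist = "CRP") {
  if (ic50_um <= 0) cs_abort("ic50 must be > 0", "parameter_error")
  if (any(concentrations_um <= 0)) {
    cs_abort("concentrations must be positive", "parameter_error")
  }
  if (noise_sd_pct < 0) cs_abort("noise SD must be >= 0", "parameter_error")
  conc <- rep(concentrations_um, each = n_replicates)
  resp <- four_pl(conc, bottom_pct, top_pct, hill, ic50_um)
  if (noise_sd_pct > 0) {
    noise <- if (is.null(seed)) {
      rnorm(length(conc), 0, noise_sd_pct)
    } else {
      withr::with_seed(as.integer(seed), rnorm(length(conc), 0, noise_sd_pct))
    }
    resp <- resp + noise
  }
  tibble::tibble(compound_id = compound_id, agonist = agonist,
                 concentration_um = conc, response_pct = resp)
}
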