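## Plate / well / trace data model and delimited-text I/O.
##
## Traces are kept in long (tidy) form: one row per (plate, well, time_s)
## sample, which is robust to ragged plates and partial layouts. Layouts are
## one CSV per plate plus a small "key: value" sidecar carrying the per-plate
## header (agonist, duplicate tag, injection time).

#' Well identifiers for a plate format
#'
#' Wells are labelled row-letter + column-number ("A1" ... "H12" for 96-well,
#' "A1" ... "AF48" for 1536-well), in row-major order, matching plate-reader
#' exports.
#'
#' @param format `"well96"` or `"well1536"`.
#' @return Character vector of well ids.
#' @export
well_ids <- function(format = c("well1536", "well96")) {
  format <- match.arg(format)
  dims <- plate_dims(format)
  rows <- row_labels(dims$nrow)
  as.vector(t(outer(rows, seq_len(dims$ncol), paste0)))
}

plate_dims <- function(format) {
  switch(format,
    well96   = list(nrow = 8L,  ncol = 12L, capacity = 96L),
    well1536 = list(nrow = 32L, ncol = 48L, capacity = 1536L),
    cs_abort(sprintf("unknown plate format '%s'", format), "format_error")
  )
}

row_labels <- function(n) {
  labs <- c(LETTERS, paste0("A", LETTERS))
  labs[seq_len(n)]
}

#' Construct a validated plate layout
#'
#' @param plate_id Plate identifier.
#' @param format Plate format (`"well96"` or `"well1536"`).
#' @param agonist Agonist injected on this plate (`"CRP"` or `"thrombin"`).
#' @param duplicate_tag `"A"` or `"B"` replicate tag.
#' @param injection_time_s Agonist injection time, seconds from recording
#'   start.
#' @param wells Tibble with columns `well`, `role` (one of `compound`,
#'   `agonist_control`, `buffer_control`), `compound_id`, `concentration_um`.
#' @param source_plate Identifier of the shared compound source plate; the
#'   A/B duplicates of both agonists of one compound plate share it. Defaults
#'   to `plate_id` with a trailing `_A`/`_B` (and agonist) suffix stripped.
#' @return A `plate_layout` object.
#' @export
plate_layout <- function(plate_id, format, agonist, duplicate_tag,
                         injection_time_s, wells, source_plate = NULL) {
  if (!format %in% c("well96", "well1536")) {
    cs_abort(sprintf("unknown plate format '%s'", format), "format_error")
  }
  if (!agonist %in% AGONISTS) {
    cs_abort(sprintf("unknown agonist '%s' (expected CRP or thrombin)", agonist),
             "format_error")
  }
  if (!duplicate_tag %in% c("A", "B")) {
    cs_abort(sprintf("duplicate_tag must be 'A' or 'B', got '%s'", duplicate_tag),
             "format_error")
  }
  injection_time_s <- as.numeric(injection_time_s)
  if (!is.finite(injection_time_s) || injection_time_s < 0) {
    cs_abort("injection_time_s must be a non-negative number", "format_error")
  }
  wells <- tibble::as_tibble(wells)
  required <- c("well", "role")
  missing <- setdiff(required, names(wells))
  if (length(missing)) {
    cs_abort(sprintf("layout is missing column(s): %s",
                     paste(missing, collapse = ", ")), "format_error")
  }
  if (!"compound_id" %in% names(wells)) wells$compound_id <- NA_character_
  if (!"concentration_um" %in% names(wells)) wells$concentration_um <- NA_real_
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[!is.na(wells$compound_id) & wells$compound_id == ""] <- NA_character_
  wells$concentration_um <- as.numeric(wells$concentration_um)

  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role)) {
    cs_abort(sprintf("unknown well role(s): %s", paste(bad_role, collapse = ", ")),
             "format_error")
  }
  dims <- plate_dims(format)
  if (nrow(wells) > dims$capacity) {
    cs_abort(sprintf("layout has %d wells, exceeding %s capacity %d",
                     nrow(wells), format, dims$capacity), "data_error")
  }
  bad_well <- setdiff(wells$well, well_ids(format))
  if (length(bad_well)) {
    cs_abort(sprintf("well id(s) not valid for %s: %s", format,
                     paste(head(bad_well, 5), collapse = ", ")), "data_error")
  }
  if (anyDuplicated(wells$well)) {
    cs_abort("duplicated well ids in layout", "data_error")
  }
  orphan <- wells$role == "compound" & is.na(wells$compound_id)
  if (any(orphan)) {
    cs_abort(sprintf("compound well(s) lacking a compound_id: %s",
                     paste(head(wells$well[orphan], 5), collapse = ", ")),
             "data_error")
  }

  structure(
    list(plate_id = as.character(plate_id), format = format, agonist = agonist,
         duplicate_tag = duplicate_tag, injection_time_s = injection_time_s,
         wells = wells,
         source_plate = source_plate %||% infer_source_plate(plate_id)),
    class = "plate_layout"
  )
}

infer_source_plate <- function(plate_id) {
  sub("_(CRP|thrombin)?_?(A|B)$", "", plate_id)
}

#' @export
print.plate_layout <- function(x, ...) {
  counts <- table(factor(x$wells$role, levels = WELL_ROLES))
  cat(sprintf("<plate_layout> %s (%s, %s, tag %s, injection %gs)\n",
              x$plate_id, x$format, x$agonist, x$duplicate_tag,
              x$injection_time_s))
  cat(sprintf("  wells: %d compound / %d agonist_control / %d buffer_control\n",
              counts[["compound"]], counts[["agonist_control"]],
              counts[["buffer_control"]]))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Trace I/O

#' Read kinetic fluorescence traces
#'
#' Long dialect (canonical): columns `plate`, `well`, `time_s`,
#' `fluorescence`. Wide dialect (read-only convenience): a `time_s` column
#' followed by one column per well; `plate_id` must then be supplied.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param plate_id Plate id for the wide dialect.
#' @return Tibble with columns `plate`, `well`, `time_s`, `fluorescence`,
#'   sorted by plate, well, time. Row order in the file is irrelevant.
#' @export
read_traces <- function(path, dialect = c("long", "wide"), plate_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    cs_abort(sprintf("trace file does not exist: %s", path), "format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (dialect == "wide") {
    if (is.null(plate_id)) {
      cs_abort("plate_id is required for the wide trace dialect", "format_error")
    }
    if (!"time_s" %in% names(raw)) {
      cs_abort("wide trace file is missing required column: time_s", "format_error")
    }
    raw <- tidyr::pivot_longer(raw, -"time_s", names_to = "well",
                               values_to = "fluorescence")
    raw$plate <- plate_id
  } else {
    required <- c("plate", "well", "time_s", "fluorescence")
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      cs_abort(sprintf("trace file is missing required column(s): %s",
                       paste(missing, collapse = ", ")), "format_error")
    }
  }
  for (col in c("time_s", "fluorescence")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad)) {
      # +1 for the header line
      cs_abort(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                       raw[[col]][bad[1]], col, bad[1] + 1L, basename(path)),
               "parse_error")
    }
    raw[[col]] <- val
  }
  traces <- dplyr::arrange(
    tibble::tibble(plate = as.character(raw$plate), well = as.character(raw$well),
                   time_s = raw$time_s, fluorescence = raw$fluorescence),
    .data$plate, .data$well, .data$time_s)
  validate_traces(traces, source = basename(path))
  traces
}

validate_traces <- function(traces, source = "traces", min_samples = 10L) {
  dup <- duplicated(traces[c("plate", "well", "time_s")])
  if (any(dup)) {
    k <- which(dup)[1]
    cs_abort(sprintf("duplicate sample for plate %s well %s at t = %g s in %s",
                     traces$plate[k], traces$well[k], traces$time_s[k], source),
             "data_error")
  }
  if (any(!is.finite(traces$fluorescence))) {
    cs_abort(sprintf("non-finite fluorescence values in %s", source), "data_error")
  }
  n <- dplyr::count(traces, .data$plate, .data$well)
  if (any(n$n < min_samples)) {
    k <- which(n$n < min_samples)[1]
    cs_abort(sprintf("trace %s/%s has only %d samples (>= %d required)",
                     n$plate[k], n$well[k], n$n[k], min_samples), "data_error")
  }
  invisible(traces)
}

#' Write traces in the canonical long format
#'
#' Numbers are serialized at full (round-trip) precision, so
#' `read_traces(write_traces(x))` reproduces `x` exactly.
#'
#' @param traces Long trace tibble.
#' @param path Output path.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces[c("plate", "well", "time_s", "fluorescence")], path,
                   progress = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Layout I/O

layout_meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta")
}

#' Read a plate layout (CSV + sidecar metadata)
#'
#' The CSV holds `well,role,compound_id,concentration_um`; the sidecar (same
#' basename, extension `.meta`) holds `key: value` lines with at least
#' `plate_id`, `format`, `agonist`, `duplicate_tag` and `injection_time_s`.
#'
#' @param path Path to the layout CSV.
#' @param meta_path Sidecar path; defaults to the CSV path with `.meta`.
#' @return A [plate_layout()] object.
#' @export
read_layout <- function(path, meta_path = layout_meta_path(path)) {
  if (!file.exists(path)) {
    cs_abort(sprintf("layout file does not exist: %s", path), "format_error")
  }
  if (!file.exists(meta_path)) {
    cs_abort(sprintf("layout sidecar does not exist: %s", meta_path), "format_error")
  }
  meta <- read_kv(meta_path)
  needed <- c("plate_id", "format", "agonist", "duplicate_tag", "injection_time_s")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    cs_abort(sprintf("layout sidecar %s is missing key(s): %s", basename(meta_path),
                     paste(missing, collapse = ", ")), "format_error")
  }
  wells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             well = readr::col_character(),
                             role = readr::col_character(),
                             compound_id = readr::col_character(),
                             concentration_um = readr::col_double(),
                             .default = readr::col_guess()))
  plate_layout(plate_id = meta$plate_id, format = meta$format,
               agonist = meta$agonist, duplicate_tag = meta$duplicate_tag,
               injection_time_s = as.numeric(meta$injection_time_s),
               wells = wells, source_plate = meta$source_plate)
}

#' Write a plate layout and its sidecar
#' @param layout A [plate_layout()] object.
#' @param path Output CSV path (sidecar written next to it).
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(layout$wells, path, progress = FALSE, na = "")
  meta <- c(plate_id = layout$plate_id, format = layout$format,
            agonist = layout$agonist, duplicate_tag = layout$duplicate_tag,
            injection_time_s = format(layout$injection_time_s, digits = 17),
            source_plate = layout$source_plate)
  writeLines(paste0(names(meta), ": ", meta), layout_meta_path(path))
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    cs_abort(sprintf("malformed 'key: value' line in %s: '%s'", basename(path),
                     lines[bad][1]), "format_error")
  }
  stats::setNames(as.list(trimws(vapply(kv, `[`, "", 3))),
                  trimws(vapply(kv, `[`, "", 2)))
}

## ---------------------------------------------------------------------------
## Pairing into a screen dataset

#' Pair duplicate A/B plates into a screen dataset
#'
#' For every (agonist, source plate) group there must be exactly one A and
#' one B plate, and the two must place identical compounds in identical
#' wells. Screens are run in such duplicate plates so that the difference
#' index can score reproducibility.
#'
#' @param plates List of `list(layout = <plate_layout>, traces = <tibble>)`
#'   entries, one per physical plate.
#' @param annotations Optional compound annotation tibble
#'   (`compound_id`, `library`, `admet_fail`).
#' @return A `screen_dataset` object.
#' @export
pair_plates <- function(plates, annotations = NULL) {
  keys <- vapply(plates, function(p) {
    paste(p$layout$agonist, p$layout$source_plate, sep = "/")
  }, "")
  groups <- split(plates, keys)
  orphans <- names(groups)[vapply(groups, function(g) {
    tags <- sort(vapply(g, function(p) p$layout$duplicate_tag, ""))
    !identical(tags, c("A", "B"))
  }, TRUE)]
  if (length(orphans)) {
    cs_abort(sprintf("unpaired plate group(s) (need exactly one A and one B): %s",
                     paste(orphans, collapse = ", ")), "pairing_error")
  }
  pairs <- lapply(groups, function(g) {
    tags <- vapply(g, function(p) p$layout$duplicate_tag, "")
    a <- g[[which(tags == "A")]]
    b <- g[[which(tags == "B")]]
    check_placement(a$layout, b$layout)
    check_traces_in_layout(a)
    check_traces_in_layout(b)
    list(agonist = a$layout$agonist, source_plate = a$layout$source_plate,
         layout_a = a$layout, traces_a = a$traces,
         layout_b = b$layout, traces_b = b$traces)
  })
  names(pairs) <- NULL
  structure(list(pairs = pairs, annotations = annotations),
            class = "screen_dataset")
}

check_placement <- function(la, lb) {
  a <- la$wells[order(la$wells$well), c("well", "role", "compound_id")]
  b <- lb$wells[order(lb$wells$well), c("well", "role", "compound_id")]
  if (!identical(a$well, b$well)) {
    w <- c(setdiff(a$well, b$well), setdiff(b$well, a$well))[1]
    cs_abort(sprintf("plates %s and %s differ in populated wells (first: %s)",
                     la$plate_id, lb$plate_id, w), "data_error")
  }
  same <- a$role == b$role &
    (is.na(a$compound_id) & is.na(b$compound_id) |
       (!is.na(a$compound_id) & !is.na(b$compound_id) &
          a$compound_id == b$compound_id))
  if (!all(same)) {
    cs_abort(sprintf("compound placement mismatch between %s and %s at well %s",
                     la$plate_id, lb$plate_id, a$well[!same][1]), "data_error")
  }
  invisible(TRUE)
}

check_traces_in_layout <- function(p) {
  extra <- setdiff(unique(p$traces$well), p$layout$wells$well)
  if (length(extra)) {
    cs_abort(sprintf("plate %s has trace well(s) absent from its layout: %s",
                     p$layout$plate_id, paste(head(extra, 5), collapse = ", ")),
             "data_error")
  }
  invisible(TRUE)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> %d plate pair(s)\n", length(x$pairs)))
  for (p in x$pairs) {
    cat(sprintf("  %s / %s: plates %s + %s\n", p$agonist, p$source_plate,
                p$layout_a$plate_id, p$layout_b$plate_id))
  }
  invisible(x)
}

#' Read a compound annotation table
#'
#' External annotations (compound library of origin, in-silico ADME-Tox
#' verdict). The `admet_fail` column is consumed as a boolean flag; it is
#' never computed by this package.
#'
#' @param path CSV with columns `compound_id`, `library`, `admet_fail`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("compound_id", "admet_fail"), names(ann))
  if (length(missing)) {
    cs_abort(sprintf("annotation file is missing column(s): %s",
                     paste(missing, collapse = ", ")), "format_error")
  }
  ann$admet_fail <- as.logical(ann$admet_fail)
  if (!"library" %in% names(ann)) ann$library <- NA_character_
  tibble::as_tibble(ann[c("compound_id", "library", "admet_fail")])
}

## ---------------------------------------------------------------------------
## Whole-dataset round trip

#' Write a screen dataset to a directory
#'
#' Emits per-plate trace and layout files plus a `manifest.csv` listing them,
#' and `annotations.csv` when present. [read_screen()] on the manifest
#' restores the dataset exactly.
#'
#' @param dataset A `screen_dataset`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest.
#' @export
write_screen <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in dataset$pairs) {
    for (side in c("a", "b")) {
      layout <- p[[paste0("layout_", side)]]
      traces <- p[[paste0("traces_", side)]]
      tf <- file.path(dir, paste0(layout$plate_id, "_traces.csv"))
      lf <- file.path(dir, paste0(layout$plate_id, "_layout.csv"))
      write_traces(traces, tf)
      write_layout(layout, lf)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plate_id = layout$plate_id, traces = basename(tf), layout = basename(lf))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(dplyr::bind_rows(rows), manifest, progress = FALSE)
  if (!is.null(dataset$annotations)) {
    readr::write_csv(dataset$annotations, file.path(dir, "annotations.csv"),
                     progress = FALSE)
  }
  invisible(manifest)
}

#' Read a screen dataset from a manifest
#'
#' @param manifest Path to a `manifest.csv` written by [write_screen()], with
#'   columns `plate_id`, `traces`, `layout` (paths relative to the manifest).
#' @return A `screen_dataset`.
#' @export
read_screen <- function(manifest) {
  if (!file.exists(manifest)) {
    cs_abort(sprintf("manifest does not exist: %s", manifest), "format_error")
  }
  dir <- dirname(manifest)
  mf <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("plate_id", "traces", "layout"), names(mf))
  if (length(missing)) {
    cs_abort(sprintf("manifest is missing column(s): %s",
                     paste(missing, collapse = ", ")), "format_error")
  }
  plates <- lapply(seq_len(nrow(mf)), function(i) {
    tf <- file.path(dir, mf$traces[i])
    lf <- file.path(dir, mf$layout[i])
    for (f in c(tf, lf)) {
      if (!file.exists(f)) {
        cs_abort(sprintf("manifest references a missing file: %s", f),
                 "format_error")
      }
    }
    list(layout = read_layout(lf), traces = read_traces(tf))
  })
  ann_path <- file.path(dir, "annotations.csv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  pair_plates(plates, annotations = ann)
}
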