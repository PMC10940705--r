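test_that("read_traces parses long files and ignores row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  lines <- c("plate,well,time_s,fluorescence",
             unlist(lapply(c("A1", "A2", "B1"), function(w) {
               sprintf("P1,%s,%d,%g", w, seq(0, 28, 2), 100 + seq(0, 28, 2))
             })))
  writeLines(lines, path)
  tr <- read_traces(path)
  expect_equal(nrow(tr), 45)
  expect_equal(sort(unique(tr$well)), c("A1", "A2", "B1"))
  expect_equal(tr$time_s[tr$well == "A1"], seq(0, 28, 2))

  shuffled <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  writeLines(c(lines[1], sample(lines[-1])), shuffled)
  expect_identical(read_traces(shuffled), tr)
})

test_that("read_traces error contracts: missing column, bad value, duplicates", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate,well,time_s", "P,A1,0"), p1)
  expect_error(read_traces(p1), "fluorescence", class = "calscreen_format_error")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate,well,time_s,fluorescence",
               sprintf("P,A1,%d,100", 0:8), "P,A1,NA,100"), p2)
  err <- expect_error(read_traces(p2), class = "calscreen_parse_error")
  expect_match(conditionMessage(err), "line 11")
  expect_match(conditionMessage(err), "time_s")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate,well,time_s,fluorescence",
               sprintf("P,A1,%d,100", c(0:9, 4))), p3)
  expect_error(read_traces(p3), "duplicate", class = "calscreen_data_error")
})

test_that("layouts validate roles, capacity and compound ids", {
  n <- 1280
  layout <- screen_layout(sprintf("C%04d", 1:n), "PL_CRP_A", "CRP", "A")
  counts <- table(layout$wells$role)
  expect_equal(unname(counts[["agonist_control"]]), 192)
  expect_equal(unname(counts[["buffer_control"]]), 64)
  expect_equal(unname(counts[["compound"]]), 1280)

  wells <- tibble::tibble(well = c("A1", "A2"), role = c("compound", "blank"),
                          compound_id = c("X", NA))
  expect_error(plate_layout("P", "well96", "CRP", "A", 30, wells),
               "blank", class = "calscreen_format_error")

  wells2 <- tibble::tibble(well = "A1", role = "compound", compound_id = NA)
  expect_error(plate_layout("P", "well96", "CRP", "A", 30, wells2),
               "compound_id", class = "calscreen_data_error")

  # duplicate wells per condition in a 96-well layout are fine
  wells3 <- tibble::tibble(well = c("A1", "A2", "B1", "B2"), role = "compound",
                           compound_id = c("X", "X", "Y", "Y"))
  expect_s3_class(plate_layout("P", "well96", "thrombin", "B", 30, wells3),
                  "plate_layout")
})

test_that("layout and trace round trips preserve values exactly", {
  dir <- withr::local_tempdir()
  layout <- screen_layout(sprintf("C%04d", 1:50), "RT_CRP_A", "CRP", "A",
                          source_plate = "RT")
  lp <- file.path(dir, "layout.csv")
  write_layout(layout, lp)
  back <- read_layout(lp)
  expect_equal(back$wells, layout$wells)
  expect_equal(back$injection_time_s, layout$injection_time_s)
  expect_equal(back$agonist, "CRP")
  expect_equal(back$source_plate, "RT")

  tr <- generate_trace(crp_template(), noise_sd_au = 3, seed = 42,
                       plate_id = "RT_CRP_A", well_id = "A9")
  tp <- file.path(dir, "traces.csv")
  write_traces(tr, tp)
  expect_equal(read_traces(tp), tr)
})

test_that("pair_plates pairs A/B and reports orphans and placement mismatches", {
  mk <- function(tag, ids = c("X", "Y")) {
    wells <- tibble::tibble(
      well = c("A1", "A2", paste0("B", 1:8), paste0("C", 1:8)),
      role = c("compound", "compound", rep("agonist_control", 8),
               rep("buffer_control", 8)),
      compound_id = c(ids, rep(NA, 16)))
    layout <- plate_layout(paste0("SRC1_CRP_", tag), "well96", "CRP", tag, 30,
                           wells, source_plate = "SRC1")
    traces <- dplyr::bind_rows(lapply(wells$well, function(w) {
      tibble::tibble(plate = layout$plate_id, well = w, time_s = seq(0, 58, 2),
                     fluorescence = 100)
    }))
    list(layout = layout, traces = traces)
  }
  ds <- pair_plates(list(mk("A"), mk("B")))
  expect_length(ds$pairs, 1)
  expect_equal(ds$pairs[[1]]$agonist, "CRP")

  expect_error(pair_plates(list(mk("A"))), "unpaired",
               class = "calscreen_pairing_error")

  swapped <- mk("B", ids = c("Y", "X"))
  err <- expect_error(pair_plates(list(mk("A"), swapped)),
                      class = "calscreen_data_error")
  expect_match(conditionMessage(err), "A1")
})

test_that("whole-screen write/read round trip preserves the dataset", {
  sim <- generate_screen(10, effect_spec = NULL, seed = 7, noise_sd_au = 2)
  dir <- withr::local_tempdir()
  manifest <- write_screen(sim$dataset, dir)
  back <- read_screen(manifest)
  expect_length(back$pairs, length(sim$dataset$pairs))
  key <- function(d) vapply(d$pairs, function(p) paste(p$agonist, p$source_plate), "")
  o <- match(key(sim$dataset), key(back))
  canon <- function(tr) tr[order(tr$well, tr$time_s), ]
  for (i in seq_along(sim$dataset$pairs)) {
    a <- sim$dataset$pairs[[i]]
    b <- back$pairs[[o[i]]]
    expect_equal(canon(b$traces_a), canon(a$traces_a))
    expect_equal(canon(b$traces_b), canon(a$traces_b))
    expect_equal(b$layout_a$wells, a$layout_a$wells)
  }
})
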