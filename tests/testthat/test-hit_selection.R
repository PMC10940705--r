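make_profiled_plate <- function(n_compounds = 30, seed = 1, noise = 4,
                                truth = empty_truth(), agonist = "CRP") {
  tpl <- if (agonist == "CRP") crp_template() else thrombin_template()
  lay <- screen_layout(sprintf("C%03d", seq_len(n_compounds)),
                       sprintf("HS_%s_A", agonist), agonist, "A")
  tr <- generate_plate(lay, tpl, truth, noise, seed)
  list(layout = lay, profiles = profile_plate(tr, lay))
}

test_that("normalization sets the agonist-control mean to 100%", {
  pp <- make_profiled_plate()
  norm <- normalize_to_controls(pp$profiles, pp$layout)
  ctrl <- norm$role == "agonist_control"
  for (p in paste0("pct_p", 1:7)) {
    expect_equal(mean(norm[[p]][ctrl]), 100, tolerance = 1e-9)
  }
  # percent arithmetic: compound at 1/4 of the control mean reads 25%
  i <- which(norm$role == "compound")[1]
  expect_equal(norm$pct_p2[i], norm$p2[i] / mean(norm$p2[ctrl]) * 100)
})

test_that("normalization degeneracies: zero control mean and too few controls", {
  pp <- make_profiled_plate()
  prof <- pp$profiles
  prof$p5 <- 0  # force a zero control mean
  expect_warning(norm <- normalize_to_controls(prof, pp$layout),
                 class = "calscreen_normalization_warning")
  expect_true(all(is.na(norm$pct_p5)))

  few <- prof[prof$role != "agonist_control" | seq_len(nrow(prof)) <= 5, ]
  expect_error(normalize_to_controls(few, pp$layout),
               "rejected", class = "calscreen_data_error")
})

test_that("classic Z-scores match an independent mean/SD computation", {
  pp <- make_profiled_plate(n_compounds = 20, seed = 2)
  norm <- normalize_to_controls(pp$profiles, pp$layout)
  cfg <- selection_config(z_method = "classic")
  z <- zscore_per_plate(norm, cfg)
  cmp <- z$role == "compound"
  x <- norm$pct_p2[cmp]
  expect_equal(z$z_p2[cmp], (x - mean(x)) / sd(x), tolerance = 1e-12)
  # a value equal to the plate mean has Z = 0; mean 100 / SD 10 / value 55
  # sits at (55 - 100) / 10 = -4.5, beyond the |4| activity threshold
  expect_equal((55 - 100) / 10, -4.5)
  expect_gt(abs(-4.5), cfg$z_threshold)

  const <- norm
  const$pct_p2 <- 100
  suppressWarnings(
    expect_warning(zc <- zscore_per_plate(const, cfg),
                   class = "calscreen_zscore_warning"))
  expect_true(all(zc$z_p2 == 0))
})

test_that("robust Z-scores survive planted outliers that wreck the SD", {
  truth <- tibble::tibble(compound_id = c("C001", "C002"),
                          kind = c("inhibitor", "autofluorescent"),
                          magnitude = c(0.2, 5), selectivity = "both")
  pp <- make_profiled_plate(n_compounds = 40, seed = 3, truth = truth)
  norm <- normalize_to_controls(pp$profiles, pp$layout)
  z_rob <- zscore_per_plate(norm, selection_config(z_method = "robust"))
  z_cls <- zscore_per_plate(norm, selection_config(z_method = "classic"))
  zi_rob <- z_rob$z_p2[z_rob$compound_id == "C001" & !is.na(z_rob$compound_id)]
  zi_cls <- z_cls$z_p2[z_cls$compound_id == "C001" & !is.na(z_cls$compound_id)]
  expect_lt(zi_rob, -4)              # the 80% inhibitor is called
  expect_gt(zi_cls, -4)              # classical SD is blown up by the 5x outlier
})

test_that("activity and direction calls follow the Z rules", {
  cfg <- selection_config()
  z <- c(p1 = 0, p2 = -5, p3 = 1, p4 = -1, p5 = 0, p6 = 0, p7 = -2)
  expect_equal(call_activity(z, cfg), list(active = TRUE, direction = "inhibitor"))
  z2 <- z; z2[["p2"]] <- 6
  expect_equal(call_activity(z2, cfg), list(active = TRUE, direction = "potentiator"))
  z3 <- c(p1 = 0, p2 = 0, p3 = 2, p4 = 3.9, p5 = -4.5, p6 = 1, p7 = 2)
  expect_equal(call_activity(z3, cfg)$active, TRUE)   # via p5
  expect_equal(call_activity(z3, cfg)$direction, "mixed")  # no direction param fired
  z4 <- rep(0, 7); names(z4) <- paste0("p", 1:7)
  expect_equal(call_activity(z4, cfg), list(active = FALSE, direction = "none"))
  z5 <- c(p1 = 0, p2 = -5, p3 = 0, p4 = 0, p5 = 0, p6 = 0, p7 = 5)
  expect_equal(call_activity(z5, cfg)$direction, "mixed")
})

test_that("cascade recovers planted specific inhibitors at the right stages", {
  spec <- tibble::tibble(
    kind = c("inhibitor", "inhibitor", "quencher"),
    selectivity = c("CRP_only", "both", "CRP_only"),
    magnitude = c(0.2, 0.2, 0.2),
    fraction = c(0.05, 0.02, 0.02))
  sim <- generate_screen(100, effect_spec = spec, seed = 11)
  res <- run_cascade(sim$dataset)
  truth <- sim$truth
  planted <- truth$compound_id[truth$kind == "inhibitor" &
                                 truth$selectivity == "CRP_only"]
  dual <- truth$compound_id[truth$kind == "inhibitor" & truth$selectivity == "both"]
  quench <- truth$compound_id[truth$kind == "quencher"]

  st <- res$report$agonists$CRP
  stage <- function(name) st$ids[[which(st$stage == name)]]
  # stage 3 (agonist-specific): the CRP-only inhibitors plus the CRP-only
  # quenchers (which mimic inhibition until the artifact stage)
  expect_setequal(stage("agonist_specific"), c(planted, quench))
  # dual-agonist inhibitors are active for both agonists and die at stage 3
  expect_true(all(dual %in% stage("active")))
  expect_false(any(dual %in% stage("agonist_specific")))
  # quenchers are removed exactly at the artifact stage
  expect_true(all(quench %in% stage("inhibitor")))
  expect_false(any(quench %in% stage("artifact_free")))
  expect_setequal(stage("artifact_free"), planted)

  # stage counts are non-increasing and nested
  expect_true(all(diff(st$n) <= 0))
  for (i in 2:nrow(st)) expect_true(all(st$ids[[i]] %in% st$ids[[i - 1]]))
})

test_that("ADME-Tox annotations reject flagged hits and retain unknowns", {
  spec <- tibble::tibble(kind = "inhibitor", selectivity = "CRP_only",
                         magnitude = 0.2, fraction = 0.05)
  sim <- generate_screen(60, effect_spec = spec, seed = 21)
  planted <- sort(sim$truth$compound_id[sim$truth$kind == "inhibitor"])
  ann <- tibble::tibble(compound_id = planted[1],
                        library = "synthetic", admet_fail = TRUE)
  expect_warning(res <- run_cascade(sim$dataset, annotations = ann),
                 class = "calscreen_admet_warning")
  st <- res$report$agonists$CRP
  final <- st$ids[[which(st$stage == "admet_clean")]]
  expect_false(planted[1] %in% final)
  expect_setequal(final, planted[-1])
})

test_that("report is invariant to well and plate ordering", {
  sim <- generate_screen(40, seed = 31)
  res1 <- run_cascade(sim$dataset)
  shuffled <- sim$dataset
  set.seed(99)
  shuffled$pairs <- sample(shuffled$pairs)
  for (i in seq_along(shuffled$pairs)) {
    tr <- shuffled$pairs[[i]]$traces_a
    shuffled$pairs[[i]]$traces_a <- tr[sample(nrow(tr)), ]
  }
  res2 <- run_cascade(shuffled)
  for (ag in c("CRP", "thrombin")) {
    expect_equal(res1$report$agonists[[ag]]$n, res2$report$agonists[[ag]]$n)
    for (i in seq_along(res1$report$agonists[[ag]]$ids)) {
      expect_setequal(res1$report$agonists[[ag]]$ids[[i]],
                      res2$report$agonists[[ag]]$ids[[i]])
    }
  }
})

test_that("|Z| of P2 shrinks monotonically as inhibition weakens", {
  zs <- vapply(c(0.2, 0.5, 0.8), function(mag) {
    truth <- tibble::tibble(compound_id = "C001", kind = "inhibitor",
                            magnitude = mag, selectivity = "both")
    pp <- make_profiled_plate(n_compounds = 30, seed = 13, truth = truth)
    norm <- normalize_to_controls(pp$profiles, pp$layout)
    z <- zscore_per_plate(norm)
    abs(z$z_p2[!is.na(z$compound_id) & z$compound_id == "C001"])
  }, 0)
  expect_true(all(diff(zs) < 0))
})

test_that("log2 effect matrix maps percent scale and masks non-positives", {
  eff <- tibble::tibble(compound_id = c("A", "B", "C"),
                        pct_p2 = c(100, 25, -5), pct_p7 = c(200, 50, 100))
  m <- log2_effect_matrix(eff, parameters = c("p2", "p7"))
  expect_equal(m["A", "p2"], 0)
  expect_equal(m["B", "p2"], -2)
  expect_equal(m["A", "p7"], 1)
  expect_true(is.na(m["C", "p2"]))
})
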