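test_that("a constant trace yields zero response parameters", {
  tr <- tibble::tibble(plate = "P", well = "A1", time_s = seq(0, 100, 2),
                       fluorescence = 100)
  p <- profile_trace(tr, "CRP", injection_time_s = 30)
  expect_equal(p$p1, 100)
  expect_equal(p$p4, 100)
  expect_equal(c(p$p2, p$p3, p$p5, p$p6, p$p7), rep(0, 5))
  expect_gt(p$peak_index, p$injection_index)
})

test_that("piecewise-linear trace matches the closed-form oracle", {
  p <- profile_trace(piecewise_trace(), "CRP", injection_time_s = 60)
  ex <- piecewise_expected
  expect_equal(p$p1, ex$p1, tolerance = 1e-12)
  expect_equal(p$p2, ex$p2, tolerance = 1e-12)
  expect_equal(p$p3, ex$p3, tolerance = 1e-12)
  expect_equal(p$p4, ex$p4, tolerance = 1e-12)
  expect_equal(p$p5, ex$p5, tolerance = 1e-12)
  expect_equal(p$p6, ex$p6, tolerance = 1e-12)
  expect_equal(p$p7, ex$p7, tolerance = 1e-12)
  expect_equal(p$f0, 100)
})

test_that("shift and scale invariances hold on noisy synthetic traces", {
  cfg <- profiling_config()
  for (seed in 1:5) {
    tr <- generate_trace(crp_template(), noise_sd_au = 8, seed = seed)
    p0 <- profile_trace(tr, "CRP", injection_time_s = 60, config = cfg)

    shifted <- tr
    shifted$fluorescence <- tr$fluorescence + 37.5
    ps <- profile_trace(shifted, "CRP", injection_time_s = 60, config = cfg)
    expect_equal(ps$p1, p0$p1 + 37.5)
    expect_equal(ps$p4, p0$p4 + 37.5)
    expect_equal(c(ps$p2, ps$p3, ps$p5, ps$p6, ps$p7),
                 c(p0$p2, p0$p3, p0$p5, p0$p6, p0$p7), tolerance = 1e-12)

    scaled <- tr
    scaled$fluorescence <- tr$fluorescence * 2.5
    pk <- profile_trace(scaled, "CRP", injection_time_s = 60, config = cfg)
    expect_equal(c(pk$p1, pk$p2, pk$p3, pk$p4, pk$p5, pk$p6, pk$p7),
                 2.5 * c(p0$p1, p0$p2, p0$p3, p0$p4, p0$p5, p0$p6, p0$p7),
                 tolerance = 1e-12)
  }
})

test_that("noise-free templates recover rise rate, peak and late slope", {
  cc <- generate_trace(crp_template())
  pc <- profile_trace(cc, "CRP", injection_time_s = 60)
  expect_equal(pc$p3, 4, tolerance = 1e-9)           # template rise_rate
  expect_equal(pc$p5, -0.3, tolerance = 1e-9)        # plateau slope
  expect_equal(pc$p6, -0.3, tolerance = 1e-9)
  expect_equal(cc$time_s[pc$injection_index], 60)

  tc <- generate_trace(thrombin_template())
  pt <- profile_trace(tc, "thrombin", injection_index = pc$injection_index)
  expect_equal(pt$p3, 13, tolerance = 1e-9)
  expect_equal(pt$p5, -1.2, tolerance = 1e-9)
  # thrombin slope-3 start (500 s) exceeds the 360 s trace: fit falls back
  # to the final 60 s, still on the decay line
  expect_equal(pt$p6, -1.2, tolerance = 1e-9)
})

test_that("a sustained response that never declines has slope 2 exactly 0", {
  tpl <- trace_template("CRP", plateau_slope_au_s = 0, duration_s = 660)
  p <- profile_trace(generate_trace(tpl), "CRP", injection_time_s = 60)
  expect_identical(p$p5, 0)
  expect_true(p$slope2_absent)
  # slightly declining plateau crosses the 97% response threshold eventually
  p2 <- profile_trace(generate_trace(crp_template()), "CRP",
                      injection_time_s = 60)
  expect_false(p2$slope2_absent)
  expect_lt(p2$p5, 0)
})

test_that("AUC agrees with a brute-force rectangle integral within 1%", {
  for (seed in 1:3) {
    tr <- generate_trace(crp_template(), noise_sd_au = 8, seed = seed)
    p <- profile_trace(tr, "CRP", injection_time_s = 60)
    idx <- p$injection_index:nrow(tr)
    oracle <- rect_auc_oracle(tr$time_s[idx], tr$fluorescence[idx], p$f0)
    expect_equal(p$p7, oracle, tolerance = 0.01)
  }
})

test_that("injection location: configured, auto-detected, and flat fallback", {
  tr <- generate_trace(crp_template(), noise_sd_au = 2, seed = 1)
  li <- locate_injection(tr, 60)
  expect_equal(tr$time_s[li$index], 60)
  expect_false(li$low_confidence)

  # drop planted at 58 s instead of the configured 60 s
  tpl <- trace_template("CRP", duration_s = 660)
  tr2 <- generate_trace(tpl, injection_time_s = 58, noise_sd_au = 2, seed = 2)
  auto <- locate_injection(tr2, 60, profiling_config(injection_auto = TRUE))
  expect_equal(tr2$time_s[auto$index], 58)

  flat <- tibble::tibble(plate = "P", well = "A1", time_s = seq(0, 200, 2),
                         fluorescence = seq(100, 120, length.out = 101))
  fb <- locate_injection(flat, 60, profiling_config(injection_auto = TRUE))
  expect_equal(flat$time_s[fb$index], 60)
  expect_true(fb$low_confidence)

  expect_error(locate_injection(tr, 1e5), class = "calscreen_parameter_error")
})

test_that("baseline is the terminal pre-injection window median", {
  drift <- tibble::tibble(plate = "P", well = "A1", time_s = seq(0, 100, 2),
                          fluorescence = 100 + 0.2 * seq(0, 100, 2))
  b <- compute_baseline(drift, injection_index = 31L)
  # window = samples at 50..58 s, median at 54 s -> 110.8, not the start value
  expect_equal(b$p1_baseline_au, 100 + 0.2 * 54)
  expect_equal(b$f0_au, b$p1_baseline_au)

  b1 <- compute_baseline(drift, 31L, profiling_config(baseline_window_samples = 1))
  expect_equal(b1$p1_baseline_au, 100 + 0.2 * 58)

  expect_error(compute_baseline(drift, 3L), class = "calscreen_profiling_error")
})

test_that("profile_plate profiles every well with roles attached", {
  ids <- sprintf("C%03d", 1:30)
  lay <- screen_layout(ids, "PP_CRP_A", "CRP", "A")
  tr <- generate_plate(lay, crp_template(), empty_truth(), 4, 5)
  prof <- profile_plate(tr, lay)
  expect_equal(nrow(prof), nrow(lay$wells))
  expect_setequal(unique(prof$role),
                  c("compound", "agonist_control", "buffer_control"))
  expect_true(all(prof$p2[prof$role == "agonist_control"] > 300))
  expect_true(all(prof$p2[prof$role == "buffer_control"] < 0))
})
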