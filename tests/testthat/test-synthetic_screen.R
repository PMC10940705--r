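test_that("noise-free thrombin template peaks at peak_au and decays back", {
  # zero leakage and an on-grid rise (floor 60, rise 11 AU/s -> 40 s) so the
  # sampled maximum hits peak_au exactly
  tpl <- trace_template("thrombin", baseline_au = 100, injection_drop_au = 40,
                        rise_rate_au_s = 11, peak_au = 500,
                        decay_rate_au_s = 1.2, duration_s = 360,
                        leakage_slope_au_s = 0)
  tr <- generate_trace(tpl)
  expect_equal(max(tr$fluorescence), 500)
  expect_lt(tail(tr$fluorescence, 1), 200)  # back toward baseline in 5 min
  # default template: sampled peak within one rise step of peak_au
  tr2 <- generate_trace(thrombin_template())
  expect_lte(max(tr2$fluorescence), 500)
  expect_gte(max(tr2$fluorescence), 500 - 13 * 2)
})

test_that("inhibitor magnitude scales peak-minus-baseline exactly at noise 0", {
  tpl <- crp_template()
  ref <- generate_trace(tpl)
  inh <- generate_trace(tpl, planted_effect("X", "inhibitor", 0.2, "both"))
  base <- tpl$baseline_au + tpl$leakage_slope_au_s * pmin(ref$time_s, 60)
  expect_equal(inh$fluorescence - base, 0.2 * (ref$fluorescence - base))
  pot <- generate_trace(tpl, planted_effect("X", "potentiator", 1.5, "both"))
  expect_equal(pot$fluorescence - base, 1.5 * (ref$fluorescence - base))
})

test_that("interferers scale the whole trace; failures are flat and dropless", {
  tpl <- thrombin_template()
  ref <- generate_trace(tpl)
  q <- generate_trace(tpl, planted_effect("X", "quencher", 0.2, "both"))
  expect_equal(q$fluorescence, 0.2 * ref$fluorescence)
  a <- generate_trace(tpl, planted_effect("X", "autofluorescent", 5, "both"))
  expect_equal(a$fluorescence, 5 * ref$fluorescence)
  fail <- generate_trace(tpl, planted_effect("X", "injection_failure", 1, "both"))
  expect_true(all(diff(fail$fluorescence) >= 0))       # drift only, no drop
  post <- fail$fluorescence[fail$time_s >= 60]
  expect_equal(diff(range(post)), 0)                   # flat post-injection
  # selectivity: a CRP-only effect leaves thrombin plates untouched
  sel <- generate_trace(tpl, planted_effect("X", "inhibitor", 0.2, "CRP_only"))
  expect_equal(sel$fluorescence, ref$fluorescence)
})

test_that("trace generation is seed-deterministic and validates parameters", {
  tpl <- crp_template()
  t1 <- generate_trace(tpl, noise_sd_au = 5, seed = 99)
  t2 <- generate_trace(tpl, noise_sd_au = 5, seed = 99)
  expect_identical(t1, t2)
  t3 <- generate_trace(tpl, noise_sd_au = 5, seed = 100)
  expect_false(identical(t1$fluorescence, t3$fluorescence))
  expect_error(generate_trace(tpl, noise_sd_au = -1),
               class = "calscreen_parameter_error")
  expect_error(planted_effect("X", "inhibitor", 1.2),
               class = "calscreen_parameter_error")
  expect_error(planted_effect("X", "none", 0.5),
               class = "calscreen_parameter_error")
})

test_that("generate_screen plants the requested effect counts and layout", {
  spec <- tibble::tibble(kind = "inhibitor", selectivity = "CRP_only",
                         magnitude = 0.2, fraction = 0.05)
  sim <- generate_screen(100, effect_spec = spec, seed = 7, noise_sd_au = 2)
  planted <- sim$truth[sim$truth$kind == "inhibitor", ]
  expect_equal(nrow(planted), 5)
  expect_true(all(planted$selectivity == "CRP_only"))
  expect_equal(nrow(sim$truth), 100)          # every compound in the map
  expect_length(sim$dataset$pairs, 2)         # one A/B pair per agonist
  lay <- sim$dataset$pairs[[1]]$layout_a
  expect_equal(lay$format, "well1536")
  expect_equal(sum(lay$wells$role == "agonist_control"), 192)
  expect_equal(sum(lay$wells$role == "buffer_control"), 64)

  bad <- tibble::tibble(kind = c("inhibitor", "potentiator"),
                        selectivity = "both", magnitude = c(0.5, 1.5),
                        fraction = c(0.6, 0.6))
  expect_error(generate_screen(50, effect_spec = bad, seed = 1),
               "sum", class = "calscreen_parameter_error")
})

test_that("A/B duplicates have shared placement but independent noise", {
  sim <- generate_screen(20, effect_spec = NULL, seed = 3, noise_sd_au = 5)
  p <- sim$dataset$pairs[[1]]
  expect_equal(p$layout_a$wells$compound_id, p$layout_b$wells$compound_id)
  expect_false(identical(p$traces_a$fluorescence, p$traces_b$fluorescence))
  # regenerating with the same seed is bit-identical
  sim2 <- generate_screen(20, effect_spec = NULL, seed = 3, noise_sd_au = 5)
  expect_identical(sim$dataset$pairs[[1]]$traces_a, sim2$dataset$pairs[[1]]$traces_a)
})

test_that("dose-response generator follows the 4PL", {
  d <- generate_dose_response(30, hill = 1, bottom_pct = 0, top_pct = 100,
                              concentrations_um = 30)
  expect_equal(d$response_pct, 50)   # midpoint at c = IC50
  d2 <- generate_dose_response(30, concentrations_um = 1e-6)
  expect_equal(d2$response_pct, 100, tolerance = 1e-6)  # c -> 0 gives top
  n1 <- generate_dose_response(30, concentrations_um = c(1, 10, 100),
                               noise_sd_pct = 5, seed = 4)
  n2 <- generate_dose_response(30, concentrations_um = c(1, 10, 100),
                               noise_sd_pct = 5, seed = 4)
  expect_identical(n1, n2)
  expect_error(generate_dose_response(-1, concentrations_um = 10),
               class = "calscreen_parameter_error")
})
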