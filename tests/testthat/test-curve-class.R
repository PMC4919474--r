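classify <- function(ts, th = class_thresholds()) {
  assign_curve_class(fit_hill(ts), ts, th)
}

test_that("threshold invariants are validated before any work", {
  expect_error(class_thresholds(eff_low = 90, eff_high = 80))
  expect_error(class_thresholds(r2_min = 0))
  expect_silent(class_thresholds())
})

test_that("realized efficacy is the in-range span of the fitted curve", {
  flat <- titration_series("f", std_grid, rep(0, 7))
  expect_equal(efficacy(fit_hill(flat), flat), 0, tolerance = 1e-6)

  full <- simulate_titration(ec50 = 4e-7, slope = 2, noise_sd = 0)
  expect_gt(efficacy(fit_hill(full), full), 98)

  # midpoint at the top tested concentration: about half the span realized
  half <- simulate_titration(ec50 = max(std_grid), slope = 1, noise_sd = 0)
  want <- abs(hill_response(max(std_grid), 0, -100, max(std_grid), 1) -
                hill_response(min(std_grid), 0, -100, max(std_grid), 1))
  expect_equal(efficacy(fit_hill(half), half), want, tolerance = 1e-3)
  expect_lt(abs(want - 50), 1)
})

test_that("decision rules assign the qHTS taxonomy", {
  # complete sigmoid, both plateaus, full efficacy
  cc11 <- classify(simulate_titration(ec50 = 4e-7, slope = 2, noise_sd = 0))
  expect_equal(cc11$curve_class, "CC1_1")
  expect_equal(cc11$direction, "inhibitor")

  # complete sigmoid, partial efficacy
  cc12 <- classify(simulate_titration(bottom = -55, ec50 = 4e-7, slope = 2,
                                      noise_sd = 0))
  expect_equal(cc12$curve_class, "CC1_2")

  # midpoint near the top concentration: saturating asymptote unrealized
  cc21 <- classify(simulate_titration(bottom = -170, ec50 = 0.8 * 46e-6,
                                      slope = 1, noise_sd = 0))
  expect_equal(cc21$curve_class, "CC2_1")
  cc22 <- classify(simulate_titration(bottom = -100, ec50 = 0.8 * 46e-6,
                                      slope = 1, noise_sd = 0))
  expect_equal(cc22$curve_class, "CC2_2")

  # single active point at the top concentration
  cc3 <- classify(titration_series("s", std_grid, c(rep(0, 6), -40)))
  expect_equal(cc3$curve_class, "CC3")
  expect_equal(cc3$direction, "inhibitor")

  # inactive
  cc4 <- classify(titration_series("n", std_grid, rep(0, 7)))
  expect_equal(cc4$curve_class, "CC4")
  expect_equal(cc4$direction, "inactive")

  # activator sign symmetry
  up <- classify(simulate_titration(bottom = 90, ec50 = 4e-7, slope = 2,
                                    noise_sd = 0))
  expect_equal(up$curve_class, "CC1_1")
  expect_equal(up$direction, "activator")
})

test_that("every generated series receives exactly one class", {
  sim <- simulate_screen(n = 60, noise_sd = 8, seed = 4)
  res <- run_screen_pipeline(sim$wells)$results
  expect_equal(nrow(res), 60L)
  expect_true(all(res$curve_class %in%
                    c("CC1_1", "CC1_2", "CC2_1", "CC2_2", "CC3", "CC4")))
  expect_true(all((res$curve_class == "CC4") == (res$direction == "inactive")))
  expect_true(all((res$curve_class == "CC4") == (res$quality == "none")))
})

test_that("raising eff_high only demotes full curves to partial subclasses", {
  sim <- simulate_screen(n = 80, noise_sd = 5, seed = 6)
  lo <- run_screen_pipeline(sim$wells,
                            thresholds = class_thresholds(eff_high = 80))
  hi <- run_screen_pipeline(sim$wells,
                            thresholds = class_thresholds(eff_high = 95))
  tab <- merge(lo$results, hi$results, by = "compound_id")
  changed <- tab[tab$curve_class.x != tab$curve_class.y, ]
  ok <- (changed$curve_class.x == "CC1_1" & changed$curve_class.y == "CC1_2") |
    (changed$curve_class.x == "CC2_1" & changed$curve_class.y == "CC2_2")
  expect_true(all(ok))
})

test_that("cytotoxicity is flagged inside the 25x EC50 active window", {
  th <- class_thresholds()
  ts <- simulate_titration(ec50 = 9e-8, noise_sd = 0)
  fit <- fit_hill(ts)
  expect_false(flag_cytotoxicity(ts, fit, th))          # cell activity 0

  ts$cell_activity <- rep(-80, 7)
  expect_true(flag_cytotoxicity(ts, fit, th))

  # drop only at the top concentration: inside the window when the EC50 is
  # two dilution steps below (25x EC50 = c_max), outside at four steps
  drop_top <- c(rep(0, 6), -80)
  ts2 <- simulate_titration(ec50 = max(std_grid) / 25, noise_sd = 0)
  ts2$cell_activity <- drop_top
  expect_true(flag_cytotoxicity(ts2, fit_hill(ts2), th))
  ts4 <- simulate_titration(ec50 = max(std_grid) / 625, noise_sd = 0)
  ts4$cell_activity <- drop_top
  expect_false(flag_cytotoxicity(ts4, fit_hill(ts4), th))

  # no meaningful EC50 (flat fit): every concentration is screened
  flat <- titration_series("f", std_grid, rep(0, 7),
                           cell_activity = c(rep(0, 6), -80))
  expect_true(flag_cytotoxicity(flat, fit_hill(flat), th))
})

test_that("triage promotes complete non-toxic curves and demotes the rest", {
  th <- class_thresholds()
  cc11 <- classify(simulate_titration(ec50 = 4e-7, slope = 2, noise_sd = 0))
  expect_equal(triage_quality(cc11, FALSE, FALSE, th)$quality, "high")
  expect_equal(triage_quality(cc11, TRUE, FALSE, th)$quality, "low")

  cc3 <- classify(titration_series("s", std_grid, c(rep(0, 6), -40)))
  expect_equal(triage_quality(cc3, FALSE, TRUE, th)$quality, "low")

  # partial curves need efficacy >= 50 AND series support for high quality
  cc12 <- classify(simulate_titration(bottom = -60, ec50 = 4e-7, slope = 2,
                                      noise_sd = 0))
  expect_equal(triage_quality(cc12, FALSE, TRUE, th)$quality, "high")
  expect_equal(triage_quality(cc12, FALSE, FALSE, th)$quality, "low")
  weak <- classify(simulate_titration(bottom = -40, ec50 = 4e-7, slope = 2,
                                      noise_sd = 0))
  expect_equal(triage_quality(weak, FALSE, TRUE, th)$quality, "low")
})

test_that("screen summaries aggregate and conserve counts", {
  s <- summarize_screen(legend_fixture())
  expect_equal(s$totals$hq_inhibitors, 2623)
  expect_equal(s$totals$lq_inhibitors, 9158)
  expect_equal(sum(s$counts$n), s$n_compounds)

  empty <- summarize_screen(legend_fixture()[0, ])
  expect_equal(empty$n_compounds, 0L)
  expect_equal(empty$totals$hq_inhibitors, 0)

  dup <- legend_fixture()[c(1, 1), ]
  expect_error(summarize_screen(dup), "duplicate")

  sim <- simulate_screen(n = 120, noise_sd = 6, seed = 8)
  res <- run_screen_pipeline(sim$wells, sim$fingerprints)
  tt <- res$summary$totals
  expect_equal(tt$hq_inhibitors + tt$hq_activators + tt$lq_inhibitors +
                 tt$lq_activators + tt$inactive, 120)
})
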