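test_that("plate tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_plate_df(), path, row.names = FALSE)
  w <- read_plate_table(path)
  expect_equal(nrow(w), 3L)
  expect_equal(w$role, c("sample", "neutral_control", "positive_control"))
  expect_equal(w$concentration_molar[1], 1e-6)

  # schema error names the missing column
  bad <- tiny_plate_df()
  names(bad)[names(bad) == "concentration_molar"] <- "conc"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_table(path), "concentration_molar")

  # row-level validation errors carry the row number
  bad2 <- tiny_plate_df(); bad2$ld_signal[2] <- -1
  write.csv(bad2, path, row.names = FALSE)
  expect_error(read_plate_table(path), "row 2")
  bad3 <- tiny_plate_df(); bad3$concentration_molar[1] <- 0
  write.csv(bad3, path, row.names = FALSE)
  expect_error(read_plate_table(path), "row 1")

  # write -> read -> write is byte-identical on generator output
  sim <- simulate_screen(n = 20, noise_sd = 3, seed = 1)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(sim$wells, p1)
  write_plate_table(read_plate_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("titration grid is the campaign's geometric dilution series", {
  g <- make_titration_concentrations(46e-6, 5, 7)
  expect_equal(length(g), 7L)
  expect_equal(g[7], 46e-6)
  expect_equal(g[1], 46e-6 / 5^6)           # the ~3 nM floor
  expect_true(all(diff(g) > 0))
  expect_equal(make_titration_concentrations(1e-6, 10, 2), c(1e-7, 1e-6))
  expect_error(make_titration_concentrations(46e-6, 5, 1))
})

test_that("per-cell normalization and percent activity follow the controls", {
  expect_equal(ld_per_cell(10, 2), 5)
  expect_equal(ld_per_cell(0, 5), 0)
  expect_true(is.na(ld_per_cell(7, 0)))     # unevaluable, not an error

  expect_equal(percent_activity(1.0, 1.0, 0.2), 0)
  expect_equal(percent_activity(0.2, 1.0, 0.2), -100)
  expect_equal(percent_activity(0.6, 1.0, 0.2), -50)
  expect_error(percent_activity(0.5, 1.0, 1.0), "undefined")
})

test_that("percent activity is invariant under joint affine rescaling", {
  wells <- multi_plate_df(activity = c(-2, -8, -25, -60, -85, -95, -98))
  base <- assemble_titrations(wells)[[1]]
  for (par in list(c(3, 0.4), c(0.25, 1.2), c(10, 0))) {
    scaled <- wells
    ldpc <- scaled$ld_signal / scaled$cell_signal
    scaled$ld_signal <- (par[1] * ldpc + par[2]) * scaled$cell_signal
    got <- assemble_titrations(scaled)[[1]]
    expect_equal(got$activity, base$activity, tolerance = 1e-10)
  }
})

test_that("titrations assemble one series per compound, median-collapsed", {
  wells <- multi_plate_df()
  ts <- assemble_titrations(wells)
  expect_length(ts, 1L)
  expect_equal(ts[[1]]$concentrations, std_grid)
  expect_equal(ts[[1]]$activity, rep(-50, 7), tolerance = 1e-10)

  # replicate wells at one concentration collapse to their median
  extra <- data.frame(plate = "P1", well = "S2", compound_id = "CMPX",
                      role = "sample", concentration_molar = std_grid[1],
                      ld_signal = (1 - 0.40 * 0.8) * 400, cell_signal = 400,
                      stringsAsFactors = FALSE)
  got <- assemble_titrations(rbind(wells, extra))[[1]]
  expect_equal(got$activity[1], -45, tolerance = 1e-10)  # median(-50,-40)

  # count equals the number of distinct sample compounds
  sim <- simulate_screen(n = 100, seed = 2)
  series <- assemble_titrations(sim$wells)
  expect_length(series, 100L)
  expect_true(all(vapply(series, function(s) length(s$concentrations),
                         integer(1)) == 7L))

  # plate without neutral controls is named in the error
  orphan <- wells[!(wells$plate == "P3" & wells$role == "neutral_control"), ]
  expect_error(assemble_titrations(orphan), "P3")
})

test_that("titration series invariants are enforced", {
  expect_error(titration_series("x", c(2e-9, 1e-9, 3e-9), rep(0, 3)),
               "increasing")
  expect_error(titration_series("x", std_grid, rep(0, 7),
                                mask = c(TRUE, TRUE, rep(FALSE, 5))),
               "one point")
})
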