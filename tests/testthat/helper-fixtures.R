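# Shared fixtures, all built in code.

std_grid <- make_titration_concentrations(46e-6, 5, 7)

# per-class counts as printed in the campaign's screen summary
legend_counts <- data.frame(
  curve_class = c("CC1_1", "CC1_2", "CC1_2", "CC2_1", "CC2_2", "CC2_2",
                  "CC3"),
  quality = c("high", "high", "low", "high", "high", "low", "low"),
  n = c(248, 203, 1479, 831, 1341, 2147, 5532),
  stringsAsFactors = FALSE
)

legend_fixture <- function() {
  data.frame(
    compound_id = sprintf("CMP%05d", seq_len(sum(legend_counts$n))),
    curve_class = rep(legend_counts$curve_class, legend_counts$n),
    direction = "inhibitor",
    quality = rep(legend_counts$quality, legend_counts$n),
    stringsAsFactors = FALSE
  )
}

tiny_plate_df <- function() {
  data.frame(
    plate = "P1",
    well = c("A1", "A2", "A3"),
    compound_id = c("CMP1", "", ""),
    role = c("sample", "neutral_control", "positive_control"),
    concentration_molar = c(1e-6, 0, 0),
    ld_signal = c(300, 500, 100),
    cell_signal = c(500, 500, 500),
    stringsAsFactors = FALSE
  )
}

# one compound titrated across 7 one-concentration plates, with controls
multi_plate_df <- function(activity = rep(-50, 7), compound_id = "CMPX") {
  plates <- lapply(seq_along(std_grid), function(p) {
    ldpc <- 1 + activity[p] / 100 * (1 - 0.2)
    data.frame(
      plate = sprintf("P%d", p),
      well = c("S1", "N1", "N2", "X1", "X2"),
      compound_id = c(compound_id, "", "", "", ""),
      role = c("sample", "neutral_control", "neutral_control",
               "positive_control", "positive_control"),
      concentration_molar = c(std_grid[p], 0, 0, 0, 0),
      ld_signal = c(ldpc * 400, 400, 400, 80, 80),
      cell_signal = c(400, 400, 400, 400, 400),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, plates)
}
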