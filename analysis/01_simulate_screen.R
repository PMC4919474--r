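#!/usr/bin/env Rscript
# Stage 1: generate the synthetic primary screen.
#
# Emulates the campaign's design at desk scale: each compound titrated
# 46 uM -> ~3 nM in 1:5 steps (one concentration per plate), solvent and
# full-inhibition control wells on every plate, a cytotoxic subpopulation,
# and structural series sharing fingerprints. Ground truth is written
# alongside so stage 2 can score itself.

library(ldscreen)

n_compounds <- 500
seed <- 11

sim <- simulate_screen(n = n_compounds, noise_frac = 0.1, toxic_frac = 0.05,
                       seed = seed)

dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)
write_plate_table(sim$wells, "results/screen/plate_table.csv")
write.csv(sim$truth, "results/screen/truth.csv", row.names = FALSE)
write.csv(data.frame(compound_id = rownames(sim$fingerprints),
                     bits = apply(sim$fingerprints, 1,
                                  function(b) paste(as.integer(b),
                                                    collapse = ""))),
          "results/screen/fingerprints.csv", row.names = FALSE)

cat(sprintf(
  "Simulated %d compounds across %d plates (%d wells), %d cytotoxic.\n",
  n_compounds, length(unique(sim$wells$plate)), nrow(sim$wells),
  sum(sim$truth$toxic)))
print(table(sim$truth$curve_class))
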