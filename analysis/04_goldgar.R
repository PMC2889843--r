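#!/usr/bin/env Rscript
# Multi-marker likelihood estimate on the simulated dataset, with growth
# corrections at 1.125 and 1.5 per generation, via the full pipeline.
# Writes results/run_goldgar/ (report, per-age log-likelihood curve).

library(founderage)

res <- run_pipeline(list(
  input = "results/sim_dataset",
  methods = c("single_marker", "goldgar"),
  growth_rates = c(1.125, 1.5),
  correction = list(mode = "montecarlo", n_sims = 1000),
  grid = c(0, 200),
  seed = 101
), out_dir = "results/run_goldgar")

cat("Pipeline log:\n")
cat(paste(" ", res$log), sep = "\n")
cat("\nReport (one row per method x growth rate):\n")
print(res$report, digits = 4)
cat("\nTruth is 17 generations. The raw likelihood estimate",
    "underestimates it (growth is not in the likelihood); the additive",
    "correction, the median of the per-marker calibrated corrections,",
    "moves the estimate and both interval bounds up.\n")
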