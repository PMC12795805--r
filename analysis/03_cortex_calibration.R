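#!/usr/bin/env Rscript

# Calibrates the neocortical base state (g = 4, zeta = 400): bisects the
# background drive eta until the pyramidal population fires at the target
# 0.68 spikes/s, then re-measures over 5 full-length trials. Writes
# results/cortex_calibration.json with the search path.

suppressPackageStartupMessages(library(eislope))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

cal <- calibrate_cortex_background(master_seed = seed)

cat(sprintf("Calibrated background: eta* = %.3f (%.0f spikes/s per neuron through %.1f nS).\n",
            cal$eta, cal$bg_rate, 2.0))
cat(sprintf("Measured pyramidal rate over %d trials: %.3f +- %.3f Hz (target %.2f).\n",
            cal$n_trials, cal$rate, cal$rate_sd, cal$target))
cat("Search path:\n")
print(cal$trace, row.names = FALSE)

jsonlite::write_json(cal[c("eta", "bg_rate", "rate", "rate_sd", "rates",
                           "trace", "n_trials", "target")],
                     "results/cortex_calibration.json",
                     auto_unbox = TRUE, digits = NA, dataframe = "columns")
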