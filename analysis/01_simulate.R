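#!/usr/bin/env Rscript
# Simulate the four-phase protocol at several training durations and archive
# spikes, weight snapshots and recall-cue logs under results/runs/.
#
# The sweep runs the scaled-down network (300 E / 60 I, 3 stimuli of 20;
# see ?scaled_config) so the whole driver chain completes on a laptop; pass
# --full for the full-size 1000 E / 200 I, 5 x 40 configuration.
#
# Usage: Rscript analysis/01_simulate.R [--seed N] [--times 0,48,96] [--full]

library(sornroute)

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1]
}
seed <- as.integer(arg("--seed", "101"))
times <- as.numeric(strsplit(arg("--times", "0,48,96"), ",")[[1]])
full <- "--full" %in% args

cfg <- if (full) default_config() else scaled_config()
out_root <- file.path("results", "runs")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

message("simulating training times: ", paste(times, collapse = ", "), " s")
sweep <- training_time_sweep(cfg, times, seed = seed)

for (nm in names(sweep)) {
  dir <- file.path(out_root, nm)
  write_archive(sweep[[nm]], dir)
  n_spk <- sum(vapply(sweep[[nm]]$spikes, nrow, integer(1)))
  message(nm, ": ", n_spk, " spikes archived to ", dir)
}
message("done; analyze with 02_tuning.R / 03_decode.R / 04_weights.R")
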