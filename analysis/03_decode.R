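#!/usr/bin/env Rscript
# Decoding analysis of archived runs: accuracy versus readout subset size
# and the minimal number of readout neurons for 95% accuracy, per
# classifier. Writes results/decoding/.
#
# Usage: Rscript analysis/03_decode.R [--seed N]

library(sornroute)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 7L

run_dirs <- list.dirs(file.path("results", "runs"), recursive = FALSE)
stopifnot(length(run_dirs) > 0)
out_dir <- file.path("results", "decoding")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

acc_rows <- list(); mr_rows <- list()
for (dir in run_dirs) {
  arc <- read_archive(dir)
  n_E <- arc$config$network$n_E
  resp <- extract_responses(arc$spikes$testing, arc$cue_log, n_neurons = n_E)
  nm <- basename(dir)
  for (sz in c(2, 5, 10, 20, 40, 80)) {
    a <- decode_accuracy(resp, sz, "perceptron", seed = seed)
    acc_rows[[length(acc_rows) + 1]] <-
      data.frame(run = nm, classifier = "perceptron", subset_size = sz,
                 acc_mean = a$mean, acc_sd = a$sd)
  }
  full_acc <- decode_accuracy(resp, n_E, "perceptron", n_subsets = 1, seed = seed)
  start <- if (full_acc$mean >= 0.95) min(100L, n_E) else n_E
  for (clf in c("perceptron", "svm", "knn3")) {
    n_seq <- if (clf == "perceptron") 40L else 10L
    mr <- minimal_readout(resp, clf, n_sequences = n_seq,
                          start_size = start, seed = seed)
    mr_rows[[length(mr_rows) + 1]] <-
      data.frame(run = nm, classifier = clf, minimal_mean = mr$mean,
                 minimal_sd = mr$sd, reachable = mr$reachable)
  }
}
acc <- do.call(rbind, acc_rows); mr <- do.call(rbind, mr_rows)
write.table(acc, file.path(out_dir, "accuracy_vs_size.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mr, file.path(out_dir, "minimal_readout.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("minimal readout neurons for 95% accuracy:")
print(mr, row.names = FALSE)
message("training should shrink the minimal readout count; the three ",
        "classifiers should agree within a small factor.")
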