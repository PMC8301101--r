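#!/usr/bin/env Rscript
# Weight-structure analysis of archived runs: connection-class weight
# distributions over training, block structure of the resorted weight
# matrix, winner-take-all check between two stimulated groups, and the
# correlation-sorted cumulative weight curve. Writes results/weights/.
#
# Usage: Rscript analysis/04_weights.R

library(sornroute)

run_dirs <- list.dirs(file.path("results", "runs"), recursive = FALSE)
stopifnot(length(run_dirs) > 0)
out_dir <- file.path("results", "weights")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (dir in run_dirs) {
  arc <- read_archive(dir)
  nm <- basename(dir)
  n_E <- arc$config$network$n_E
  ee <- arc$snapshots[["pre_test"]]
  lab <- classify_connections(ee, arc$groups)
  cls_mean <- tapply(lab$weight, lab$conn_class, mean)
  write.table(weight_class_table(arc$snapshots, arc$groups),
              file.path(out_dir, paste0(nm, "_class_weights.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rs <- resort_matrix(ee, arc$groups, n_E)
  pw <- pairwise_group_weights(ee, arc$groups[[1]], arc$groups[[2]], n_E)
  resp <- extract_responses(arc$spikes$testing, arc$cue_log, n_neurons = n_E)
  cw <- suppressWarnings(correlation_weight_curve(resp, ee))
  write.table(cw$curve, file.path(out_dir, paste0(nm, "_correlation_curve.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    run = nm, t(as.matrix(cls_mean)),
    block_ratio = block_weight_ratio(ee, rs$block),
    pairwise_cor = pw$correlation,
    top_conn_frac_half_weight = cw$top_connection_frac)
}
summary <- do.call(rbind, rows)
write.table(summary, file.path(out_dir, "weights_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("weight structure by run:")
print(summary, row.names = FALSE)
message("after training: intra-stimulus and stim->reservoir classes should ",
        "dominate, the block ratio should exceed 1, the pairwise group ",
        "correlation should be negative, and a small connection fraction ",
        "should hold half the total weight.")
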