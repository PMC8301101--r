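# Run archives: self-contained plain-text dumps of a protocol run that can
# be re-analyzed without re-simulation. All tables are TSV; metadata (config,
# seeds) goes into a JSON sidecar.

#' Write a protocol run to an archive directory
#'
#' @param run `sorn_run` from [run_protocol()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name)
    write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (ph in names(run$spikes)) tsv(run$spikes[[ph]], paste0("spikes_", ph))
  for (nm in names(run$snapshots)) tsv(run$snapshots[[nm]], paste0("weights_", nm))
  tsv(run$cue_log, "cue_log")
  meta <- list(config = run$config, seed = run$seed,
               groups = run$groups,
               phases = names(run$spikes), snapshots = names(run$snapshots))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a run archive
#'
#' @param dir archive directory written by [write_archive()].
#' @return list with `spikes`, `snapshots`, `cue_log`, `groups`, `config`,
#'   `seed` (same layout as a `sorn_run`, minus the live network state).
#' @export
read_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(name)
    read.table(file.path(dir, paste0(name, ".tsv")), sep = "\t", header = TRUE)
  spikes <- lapply(meta$phases, function(ph) {
    df <- rd(paste0("spikes_", ph))
    df$time_ms <- as.numeric(df$time_ms)   # empty tables read as logical
    df$neuron <- as.integer(df$neuron)
    df
  })
  names(spikes) <- meta$phases
  snapshots <- lapply(meta$snapshots, function(nm) rd(paste0("weights_", nm)))
  names(snapshots) <- meta$snapshots
  groups <- if (is.matrix(meta$groups)) {
    # equal-sized groups come back from JSON as a matrix, one row per group
    lapply(seq_len(nrow(meta$groups)), function(i) as.integer(meta$groups[i, ]))
  } else {
    lapply(meta$groups, as.integer)
  }
  list(spikes = spikes, snapshots = snapshots, cue_log = rd("cue_log"),
       groups = groups, config = meta$config, seed = meta$seed)
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Simulates the four-phase protocol, extracts post-cue responses, computes
#' the tuning profile, decodes from random readout subsets, and analyzes
#' the weight structure; optionally archives everything under `out_dir`.
#'
#' @param cfg configuration list.
#' @param seed master seed; the build uses `seed`, the protocol `seed + 1`
#'   and the decoding analyses `seed + 2` (hierarchical, so stages can be
#'   re-randomized independently).
#' @param out_dir optional archive directory.
#' @param decode_sizes readout subset sizes at which to report decoding
#'   accuracy.
#' @return list with `run`, `responses`, `profile`, `decoding` (tidy data
#'   frame), `weights` (classified EE table, block ratio, correlation
#'   curve).
#' @export
run_pipeline <- function(cfg = scaled_config(), seed = 1L, out_dir = NULL,
                         decode_sizes = c(5, 10, 20, 40)) {
  rep <- validate_config(cfg)
  if (any(rep$level == "error"))
    stop("invalid configuration: ",
         paste(rep$message[rep$level == "error"], collapse = "; "))
  net <- build_network(cfg, seed = seed)
  run <- run_protocol(net, seed = seed + 1L)
  responses <- extract_responses(run$spikes$testing, run$cue_log,
                                 n_neurons = cfg$network$n_E)
  profile <- tuning_profile(responses)
  set.seed(seed + 2L)
  decoding <- do.call(rbind, lapply(decode_sizes, function(sz) {
    acc <- decode_accuracy(responses, sz, "perceptron",
                           seed = sample.int(2^30, 1))
    data.frame(classifier = "perceptron", subset_size = sz,
               acc_mean = acc$mean, acc_sd = acc$sd)
  }))
  ee_final <- run$snapshots[["pre_test"]]
  classified <- classify_connections(ee_final, run$groups)
  rs <- resort_matrix(ee_final, run$groups, cfg$network$n_E)
  weights <- list(classified = classified,
                  block_ratio = block_weight_ratio(ee_final, rs$block),
                  correlation_curve = correlation_weight_curve(responses, ee_final))
  if (!is.null(out_dir)) {
    write_archive(run, out_dir)
    write.table(decoding, file.path(out_dir, "decoding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(neuron = seq_len(nrow(profile$prob)),
                           n_tunings = profile$n_tunings, mi = profile$mi),
                file.path(out_dir, "tuning.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(run = run, responses = responses, profile = profile,
       decoding = decoding, weights = weights)
}
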