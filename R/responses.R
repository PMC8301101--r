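#' Extract post-cue spiking responses
#'
#' Bins each neuron's spikes within the half-open window
#' `[cue_time, cue_time + window_ms)` after every recall cue into
#' `window_ms / bin_ms` half-open bins (default 2.5 ms in 0.5 ms bins), and
#' derives the binary response indicator (at least one spike in the window).
#'
#' @param spikes data frame (`time_ms`, `neuron`).
#' @param cue_log data frame (`time_ms`, `stimulus`), times on the same
#'   clock as `spikes`; consecutive cues must be at least `window_ms` apart.
#' @param n_neurons number of neurons to tabulate (response rows cover ids
#'   `1..n_neurons` even if silent).
#' @param window_ms,bin_ms response window and bin width in ms.
#' @return An object of class `response_table`: list with `stimulus`
#'   (per-trial stimulus id), `counts` (trials x neurons x bins array) and
#'   `indicator` (trials x neurons binary matrix).
#' @export
extract_responses <- function(spikes, cue_log, n_neurons,
                              window_ms = 2.5, bin_ms = 0.5) {
  stopifnot(window_ms > 0, bin_ms > 0)
  cue_log <- cue_log[order(cue_log$time_ms), , drop = FALSE]
  if (nrow(cue_log) > 1 && any(diff(cue_log$time_ms) < window_ms))
    stop("overlapping response windows: cue inter-arrival below ", window_ms, " ms")
  n_trials <- nrow(cue_log)
  n_bins <- as.integer(round(window_ms / bin_ms))
  counts <- array(0L, dim = c(n_trials, n_neurons, n_bins))
  if (nrow(spikes) > 0 && n_trials > 0) {
    trial <- findInterval(spikes$time_ms, cue_log$time_ms)
    off <- spikes$time_ms - cue_log$time_ms[pmax(trial, 1L)]
    keep <- trial >= 1L & off < window_ms & spikes$neuron <= n_neurons
    if (any(keep)) {
      tr <- trial[keep]; nn <- spikes$neuron[keep]
      bin <- pmin(floor(off[keep] / bin_ms), n_bins - 1) + 1L
      idx <- cbind(tr, nn, bin)
      # accumulate possibly repeated (trial, neuron, bin) triplets
      key <- (tr - 1) + n_trials * ((nn - 1) + n_neurons * (bin - 1))
      tab <- table(key)
      flat <- as.integer(names(tab))
      counts[flat + 1L] <- as.integer(tab)
    }
  }
  indicator <- (apply(counts, c(1, 2), sum) > 0) * 1L
  structure(list(stimulus = cue_log$stimulus, counts = counts,
                 indicator = indicator,
                 window_ms = window_ms, bin_ms = bin_ms),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat("<response_table> ", length(x$stimulus), " trials x ",
      ncol(x$indicator), " neurons, ", dim(x$counts)[3], " bins of ",
      x$bin_ms, " ms\n", sep = "")
  invisible(x)
}

#' Per-neuron stimulus response probabilities
#'
#' Estimates, for each neuron and each stimulus, the probability of spiking
#' at least once within the post-cue window: the fraction of that stimulus's
#' trials with a positive response indicator.
#'
#' @param responses `response_table`.
#' @return matrix (neurons x stimuli) of probabilities `p_i`.
#' @export
response_probabilities <- function(responses) {
  stims <- sort(unique(responses$stimulus))
  n_per <- tabulate(match(responses$stimulus, stims))
  if (any(n_per == 0)) stop("stimulus with zero trials")
  p <- vapply(stims, function(s)
    colMeans(responses$indicator[responses$stimulus == s, , drop = FALSE]),
    numeric(ncol(responses$indicator)))
  colnames(p) <- stims
  p
}

#' Tuning counts at a response-probability threshold
#'
#' A neuron is tuned to stimulus i when its response probability strictly
#' exceeds the threshold (default 20%). Returns the number of tunings per
#' neuron and the population fraction at each tuning count.
#'
#' @param prob matrix (neurons x stimuli) from [response_probabilities()].
#' @param threshold tuning threshold in `[0, 1]`.
#' @return list with `n_tunings` (per neuron), `fractions` (named vector
#'   over `0..n_stim`, summing to 1) and `threshold`.
#' @export
tuning_counts <- function(prob, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  n_stim <- ncol(prob)
  n_tun <- rowSums(prob > threshold)
  frac <- tabulate(n_tun + 1L, nbins = n_stim + 1L) / nrow(prob)
  names(frac) <- 0:n_stim
  list(n_tunings = n_tun, fractions = frac, threshold = threshold)
}

# binary entropy in bits with 0*log2(0) = 0
H2 <- function(p) {
  h <- function(q) ifelse(q > 0, -q * log2(q), 0)
  h(p) + h(1 - p)
}

#' Mutual information of a binary response with the stimulus
#'
#' For a neuron with response probabilities `p = (p_1, ..., p_nstim)` under
#' a uniform stimulus prior, the stimulus/response mutual information is
#' `MI = H2(mean(p)) - mean(H2(p))` bits, where `H2` is the binary entropy.
#' MI is bounded by 1 bit (attained when the pooled spiking probability is
#' 1/2 and every conditional response is deterministic).
#'
#' `variant = "paper_expression"` evaluates the reduced expression used in
#' the source analysis's worked example, which keeps only the `-p*log2(p)`
#' halves of the entropies: for a cell responding only to its preferred one
#' of five stimuli it gives `-0.2*log2(0.2) = 0.46` bit, whereas the full
#' binary entropy gives `H2(0.2) = 0.72` bit.
#'
#' @param p vector (or neurons x stimuli matrix) of response probabilities.
#' @param variant `"standard"` (full binary entropy) or
#'   `"paper_expression"`.
#' @return MI in bits (vector if `p` is a matrix).
#' @export
mutual_information <- function(p, variant = c("standard", "paper_expression")) {
  variant <- match.arg(variant)
  ent <- if (variant == "standard") H2 else function(q) ifelse(q > 0, -q * log2(q), 0)
  if (is.matrix(p)) {
    stopifnot(all(p >= 0 & p <= 1))
    ent(rowMeans(p)) - rowMeans(ent(p))
  } else {
    stopifnot(all(p >= 0 & p <= 1))
    ent(mean(p)) - mean(ent(p))
  }
}

#' Full tuning profile of a response table
#'
#' Convenience wrapper bundling response probabilities, tuning counts and
#' per-neuron mutual information.
#'
#' @param responses `response_table`.
#' @param threshold tuning threshold.
#' @return list of class `tuning_profile` with `prob`, `n_tunings`,
#'   `fractions`, `mi` (standard) and `mi_paper` (reduced expression).
#' @export
tuning_profile <- function(responses, threshold = 0.2) {
  prob <- response_probabilities(responses)
  tc <- tuning_counts(prob, threshold)
  structure(list(prob = prob, n_tunings = tc$n_tunings,
                 fractions = tc$fractions, threshold = threshold,
                 mi = mutual_information(prob),
                 mi_paper = mutual_information(prob, "paper_expression")),
            class = "tuning_profile")
}
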