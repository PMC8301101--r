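#' Generate synthetic tuned-Bernoulli response tables
#'
#' Emulates the response structure the analyses assume: a fraction `f` of
#' neurons is tuned, each to a uniformly random preferred stimulus, and
#' spikes within the post-cue window with probability `p_on` for its
#' preferred stimulus and `p_off` otherwise; untuned neurons spike with
#' `p_off` for every stimulus. A responding trial contributes one spike
#' whose bin is drawn from a jitter model: a discretized Gaussian centred
#' on the middle bin (sd one bin), emulating the small trial-to-trial
#' latency jitter of recall responses, or a uniform bin.
#'
#' @param n_neurons number of neurons.
#' @param n_stim number of stimuli.
#' @param f tuned fraction.
#' @param p_on,p_off response probabilities (`0 <= p_off <= p_on <= 1`).
#' @param trials_per_stimulus trials per stimulus (balanced design).
#' @param jitter `"gaussian"` or `"uniform"` bin placement.
#' @param n_bins bins per response window.
#' @param seed integer seed.
#' @return list with `responses` (a `response_table`) and `tuning`
#'   (per-neuron preferred stimulus, `NA` for untuned neurons).
#' @export
generate_responses <- function(n_neurons, n_stim = 5L, f = 1, p_on = 0.9,
                               p_off = 0.05, trials_per_stimulus = 40L,
                               jitter = c("gaussian", "uniform"),
                               n_bins = 5L, seed = 1L) {
  stopifnot(f >= 0, f <= 1, p_off >= 0, p_off <= p_on, p_on <= 1)
  jitter <- match.arg(jitter)
  set.seed(seed)
  n_tuned <- round(f * n_neurons)
  tuning <- rep(NA_integer_, n_neurons)
  if (n_tuned > 0)
    tuning[sample.int(n_neurons, n_tuned)] <- sample.int(n_stim, n_tuned, replace = TRUE)

  stimulus <- rep_len(seq_len(n_stim), n_stim * trials_per_stimulus)
  n_trials <- length(stimulus)

  pmat <- matrix(p_off, n_trials, n_neurons)
  tuned_idx <- which(!is.na(tuning))
  for (j in tuned_idx) pmat[stimulus == tuning[j], j] <- p_on
  indicator <- matrix(rbinom(n_trials * n_neurons, 1L, as.vector(pmat)),
                      n_trials, n_neurons)

  bin_prob <- switch(jitter,
    gaussian = {
      centers <- seq_len(n_bins) - 1
      w <- exp(-(centers - (n_bins - 1) / 2)^2 / 2)
      w / sum(w)
    },
    uniform = rep(1 / n_bins, n_bins))
  counts <- array(0L, dim = c(n_trials, n_neurons, n_bins))
  resp <- which(indicator == 1L)
  if (length(resp)) {
    bins <- sample.int(n_bins, length(resp), replace = TRUE, prob = bin_prob)
    counts[resp + (bins - 1L) * (n_trials * n_neurons)] <- 1L
  }
  responses <- structure(list(stimulus = stimulus, counts = counts,
                              indicator = indicator,
                              window_ms = 2.5, bin_ms = 2.5 / n_bins),
                         class = "response_table")
  list(responses = responses, tuning = tuning)
}

#' Monte-Carlo minimal readout count
#'
#' Simulates the readout draw process directly (each draw is tuned with
#' probability `f`, with a uniformly random preferred stimulus, and assumed
#' perfectly reliable: `p_on = 1`, `p_off = 0`): for each replicate, draws
#' neurons until at least `n_stim - 1` distinct tunings are covered, then
#' returns the smallest `k` whose empirical coverage probability exceeds
#' `certainty`. Serves as the independent check of [min_readouts()].
#'
#' @param f tuned fraction (> 0).
#' @param n_stim number of stimuli.
#' @param certainty required coverage probability.
#' @param n_rep Monte-Carlo replicates.
#' @param seed integer seed.
#' @return minimal `k` (integer).
#' @export
empirical_min_readouts <- function(f, n_stim, certainty = 0.95,
                                   n_rep = 10000L, seed = 1L) {
  stopifnot(f > 0, n_stim >= 2)
  set.seed(seed)
  need <- n_stim - 1L
  draws_until_covered <- function() {
    chunk <- max(64L, as.integer(ceiling(4 * need / f)))
    offset <- 0L
    seen <- logical(n_stim)
    repeat {
      tuned <- runif(chunk) < f
      cat_draw <- ifelse(tuned, sample.int(n_stim, chunk, replace = TRUE), 0L)
      is_new <- cat_draw > 0L & !seen[pmax(cat_draw, 1L)] & !duplicated(cat_draw)
      n_distinct <- sum(seen) + cumsum(is_new)
      hit <- which(n_distinct >= need)
      if (length(hit)) return(offset + hit[1L])
      seen[cat_draw[cat_draw > 0L]] <- TRUE
      offset <- offset + chunk
    }
  }
  k_needed <- vapply(seq_len(n_rep), function(r) draws_until_covered(), integer(1))
  cdf <- cumsum(tabulate(k_needed, nbins = max(k_needed))) / n_rep
  min(which(cdf > certainty))
}
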