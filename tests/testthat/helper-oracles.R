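# Independent oracles used across tests.

# Decoding probability by joint enumeration over all population spike
# counts (independent binomial populations; ties lose).
enum_p_decode <- function(p_on, p_off, n_con, n_stim) {
  counts <- expand.grid(rep(list(0:n_con), n_stim))
  probs <- apply(counts, 1, function(k) {
    dbinom(k[1], n_con, p_on) * prod(dbinom(k[-1], n_con, p_off))
  })
  win <- apply(counts, 1, function(k) k[1] > max(k[-1]))
  sum(probs[win])
}

# Decoding probability by Monte-Carlo sampling of Bernoulli populations.
mc_p_decode <- function(p_on, p_off, n_con, n_stim, n_draws = 1e5) {
  tuned <- rbinom(n_draws, n_con, p_on)
  others <- matrix(rbinom(n_draws * (n_stim - 1), n_con, p_off),
                   n_draws, n_stim - 1)
  mean(tuned > apply(others, 1, max))
}

# Coverage probability by Monte-Carlo simulation of the draw process.
mc_coverage <- function(k, f, n_stim, n_rep = 1e5) {
  mean(replicate(n_rep, {
    tuned <- runif(k) < f
    cats <- unique(sample.int(n_stim, k, replace = TRUE)[tuned])
    length(cats) >= n_stim - 1
  }))
}

# 3-sigma binomial tolerance for a Monte-Carlo probability estimate
mc_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
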