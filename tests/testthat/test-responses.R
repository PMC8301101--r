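test_that("post-cue spikes land in half-open bins", {
  cues <- data.frame(time_ms = c(100, 600), stimulus = c(1, 2))
  spikes <- data.frame(
    time_ms = c(101.0,   # 1.0 ms after cue 1 -> bin 3 (0-indexed bin 2)
                100.0,   # exactly at cue -> bin 1
                102.5,   # exactly at window end -> excluded
                99.9,    # before cue -> excluded
                600.4),  # 0.4 ms after cue 2 -> bin 1
    neuron = c(1, 1, 1, 1, 2))
  rt <- extract_responses(spikes, cues, n_neurons = 2)
  expect_equal(dim(rt$counts), c(2, 2, 5))
  expect_equal(rt$counts[1, 1, ], c(1L, 0L, 1L, 0L, 0L))
  expect_equal(sum(rt$counts[1, 2, ]), 0L)
  expect_equal(rt$counts[2, 2, ], c(1L, 0L, 0L, 0L, 0L))
  expect_equal(rt$indicator, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_error(extract_responses(spikes, data.frame(time_ms = c(0, 1), stimulus = 1:2),
                                 n_neurons = 2),
               "overlapping")
})

test_that("response probabilities are per-stimulus trial fractions", {
  # neuron 1 fires on every stimulus-1 trial, never otherwise
  cues <- data.frame(time_ms = seq(0, 900, by = 100),
                     stimulus = rep(1:2, 5))
  spikes <- data.frame(time_ms = cues$time_ms[cues$stimulus == 1] + 0.7,
                       neuron = 1)
  rt <- extract_responses(spikes, cues, n_neurons = 2)
  p <- response_probabilities(rt)
  expect_equal(p[1, ], c("1" = 1, "2" = 0))
  expect_equal(p[2, ], c("1" = 0, "2" = 0))
})

test_that("synthetic response probabilities recover generator parameters", {
  g <- generate_responses(n_neurons = 200, n_stim = 5, f = 1, p_on = 0.8,
                          p_off = 0.1, trials_per_stimulus = 40, seed = 5)
  p <- response_probabilities(g$responses)
  n_tr <- 40
  p_on_hat <- p[cbind(seq_len(200), g$tuning)]
  within_on <- abs(p_on_hat - 0.8) < 3 * sqrt(0.8 * 0.2 / n_tr)
  expect_gt(mean(within_on), 0.95)
  off_mask <- matrix(TRUE, 200, 5); off_mask[cbind(seq_len(200), g$tuning)] <- FALSE
  p_off_hat <- p[off_mask]
  expect_lt(abs(mean(p_off_hat) - 0.1), 0.02)
})

test_that("tuning counts use a strict threshold and sweep monotonically", {
  p <- rbind(c(1, 0, 0, 0, 0),
             c(0.19, 0.19, 0.19, 0.19, 0.19),
             c(0.5, 0.5, 0.1, 0, 0))
  tc <- tuning_counts(p, threshold = 0.2)
  expect_equal(unname(tc$n_tunings), c(1, 0, 2))
  expect_equal(sum(tc$fractions), 1)
  expect_error(tuning_counts(p, threshold = 1.5), "threshold")
  # n_tunings is non-increasing in the threshold for every neuron
  set.seed(3)
  pm <- matrix(runif(50 * 5), 50, 5)
  thetas <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(thetas, function(th) tuning_counts(pm, th)$n_tunings,
                   numeric(50))
  expect_true(all(apply(counts, 1, function(x) all(diff(x) <= 0))))
})

test_that("mutual information reproduces the analytic worked example", {
  # perfectly tuned cell, one of five equiprobable stimuli
  p <- c(1, 0, 0, 0, 0)
  expect_equal(mutual_information(p, "paper_expression"),
               -0.2 * log2(0.2), tolerance = 1e-12)          # 0.46 bit
  expect_equal(round(mutual_information(p, "paper_expression"), 2), 0.46)
  expect_equal(mutual_information(p, "standard"),
               -0.2 * log2(0.2) - 0.8 * log2(0.8), tolerance = 1e-12)  # 0.72 bit
  # stimulus-independent responses carry no information
  expect_equal(mutual_information(rep(0.3, 5)), 0)
  # 1 bit bound, attained at pooled probability 1/2 with deterministic responses
  expect_equal(mutual_information(c(1, 0)), 1)
  set.seed(8)
  for (i in 1:50) {
    p <- runif(5)
    mi <- mutual_information(p)
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    expect_equal(mutual_information(sample(p)), mi)  # label-permutation invariant
  }
})

test_that("matrix and vector mutual information agree", {
  pm <- rbind(c(1, 0, 0, 0, 0), c(0.4, 0.4, 0.4, 0.4, 0.4), c(0.9, 0.1, 0, 0, 0.2))
  expect_equal(mutual_information(pm),
               apply(pm, 1, mutual_information))
})
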