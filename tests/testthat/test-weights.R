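# Weight-structure analyses on constructed synapse tables (simulation-level
# assertions live in the acceptance tests).

two_group_setup <- function() {
  groups <- list(1:3, 4:6)  # 10 neurons: 2 groups of 3, reservoir 7:10
  syn <- data.frame(
    pre  = c(1, 2, 1, 4, 1, 7, 7, 8, 4),
    post = c(2, 3, 4, 5, 7, 1, 8, 9, 8),
    weight = 1, class = "EE")
  list(groups = groups, syn = syn)
}

test_that("connection classification partitions the EE synapses", {
  s <- two_group_setup()
  lab <- classify_connections(s$syn, s$groups)
  expect_equal(as.character(lab$conn_class),
               c("intra_stimulus", "intra_stimulus", "inter_stimulus",
                 "intra_stimulus", "stim_to_reservoir", "reservoir_to_stim",
                 "reservoir", "reservoir", "stim_to_reservoir"))
  expect_equal(sum(table(lab$conn_class)), nrow(s$syn))  # exhaustive partition
  expect_error(classify_connections(s$syn, list(1:3, 3:5)), "two stimulus groups")
})

test_that("resorting is stable, idempotent and groups by dominant input", {
  groups <- list(1:2, 3:4)
  # neurons 5,6 get most input from group 1; neuron 7 from group 2
  syn <- data.frame(pre = c(1, 2, 1, 3, 3, 4),
                    post = c(5, 5, 6, 6, 7, 7),
                    weight = c(5, 5, 3, 1, 4, 4), class = "EE")
  rs <- resort_matrix(syn, groups, n_exc = 7)
  expect_equal(rs$block[5:7], c(1, 1, 2))
  # within a block, decreasing cumulative input weight
  b1 <- rs$order[rs$block[rs$order] == 1]
  expect_true(all(diff(rs$input_weight[b1]) <= 0))
  rs2 <- resort_matrix(syn[order(syn$weight), ], groups, 7)
  expect_equal(rs2$order, rs$order)  # permutation independent of row order
})

test_that("block weight ratio is near 1 for unstructured weights", {
  set.seed(14)
  n <- 60
  syn <- data.frame(pre = sample(n, 600, TRUE), post = sample(n, 600, TRUE),
                    weight = runif(600, 0.4, 0.6), class = "EE")
  syn <- syn[syn$pre != syn$post, ]
  groups <- list(1:10, 11:20)
  rs <- resort_matrix(syn, groups, n)
  ratio <- block_weight_ratio(syn, rs$block)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.2)
})

test_that("pairwise group weights expose winner-take-all structure", {
  groups <- list(1:2, 3:4)
  # winner-take-all: neurons 5..8 draw weight from exactly one group
  syn <- data.frame(pre = c(1, 2, 1, 2, 3, 4, 3, 4),
                    post = c(5, 5, 6, 6, 7, 7, 8, 8),
                    weight = 5, class = "EE")
  pw <- pairwise_group_weights(syn, groups[[1]], groups[[2]], n_exc = 8)
  on_axis <- pw$table$mean_a == 0 | pw$table$mean_b == 0
  expect_true(all(on_axis))
  expect_error(pairwise_group_weights(syn, 1:3, 3:4, 8), "overlap")
})

test_that("uniform weights put the pairwise means at the expected point", {
  set.seed(15)
  n <- 80; groups <- list(1:10, 11:20)
  pairs <- expand.grid(pre = 1:n, post = 1:n)
  pairs <- pairs[pairs$pre != pairs$post & runif(nrow(pairs)) < 0.3, ]
  syn <- data.frame(pairs, weight = 0.5, class = "EE")
  pw <- pairwise_group_weights(syn, groups[[1]], groups[[2]], n_exc = n)
  got <- pw$table[21:n, ]
  # mean over existing synapses of constant weight 0.5 is 0.5 wherever defined
  expect_true(all(got$mean_a[got$mean_a > 0] == 0.5))
  expect_true(all(got$mean_b[got$mean_b > 0] == 0.5))
})

test_that("correlation-sorted cumulative curves behave as distributions", {
  g <- generate_responses(30, n_stim = 3, f = 1, p_on = 0.9, p_off = 0.1,
                          trials_per_stimulus = 30, seed = 16)
  set.seed(17)
  syn <- data.frame(pre = sample(30, 200, TRUE), post = sample(30, 200, TRUE),
                    weight = runif(200, 0.1, 1), class = "EE")
  syn <- syn[syn$pre != syn$post, ]
  cw <- correlation_weight_curve(g$responses, syn)
  curve <- cw$curve
  expect_true(all(diff(curve$cum_weight_frac) >= -1e-12))
  expect_true(all(diff(curve$cum_count_frac) >= 0))
  expect_equal(curve$cum_weight_frac[nrow(curve)], 1)
  expect_equal(curve$cum_count_frac[nrow(curve)], 1)
  expect_true(all(diff(curve$correlation) >= 0))
  # equal weights: the two curves coincide
  syn_eq <- syn; syn_eq$weight <- 1
  cw_eq <- correlation_weight_curve(g$responses, syn_eq)
  expect_equal(cw_eq$curve$cum_weight_frac, cw_eq$curve$cum_count_frac)
  # doubling the most-correlated synapse lifts the top of the weight curve
  syn2 <- syn
  i_top <- which.max(suppressWarnings(cor(g$responses$indicator))[cbind(syn$pre, syn$post)])
  syn2$weight[i_top] <- syn2$weight[i_top] * 2
  cw2 <- correlation_weight_curve(g$responses, syn2)
  n <- nrow(cw$curve)
  expect_lt(cw2$curve$cum_weight_frac[n - 1], cw$curve$cum_weight_frac[n - 1])
})

test_that("zero-variance response pairs are kept at correlation zero with a warning", {
  g <- generate_responses(10, n_stim = 2, f = 1, p_on = 1, p_off = 0,
                          trials_per_stimulus = 5, seed = 18)
  g$responses$indicator[, 1] <- 0L  # silence neuron 1
  syn <- data.frame(pre = c(1, 2), post = c(2, 3), weight = 1, class = "EE")
  expect_warning(cw <- correlation_weight_curve(g$responses, syn), "zero-variance")
  expect_true(0 %in% cw$curve$correlation)
})
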