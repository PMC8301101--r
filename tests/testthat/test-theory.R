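test_that("p_decode matches exhaustive enumeration for small populations", {
  expect_equal(p_decode(0.8, 0.1, 1, 2), 0.72)  # 0.8 * P(other silent)
  for (n_con in 1:3) for (n_stim in c(2, 3, 5)) {
    for (pp in list(c(0.9, 0.05), c(0.7, 0.3), c(0.5, 0.5), c(1, 0))) {
      expect_equal(p_decode(pp[1], pp[2], n_con, n_stim),
                   enum_p_decode(pp[1], pp[2], n_con, n_stim),
                   tolerance = 1e-12,
                   label = sprintf("n_con=%d n_stim=%d", n_con, n_stim))
    }
  }
})

test_that("p_decode is exact for perfectly tuned responses and matches Monte Carlo", {
  expect_equal(p_decode(1, 0, 1, 5), 1)
  expect_equal(p_decode(1, 0, 7, 2), 1)
  set.seed(11)
  for (case in list(c(0.8, 0.1, 5, 5), c(0.6, 0.2, 10, 3))) {
    p <- p_decode(case[1], case[2], case[3], case[4])
    phat <- mc_p_decode(case[1], case[2], case[3], case[4])
    expect_lt(abs(p - phat), mc_tol(p, 1e5))
  }
})

test_that("p_decode is monotone in its arguments", {
  grid <- seq(0.3, 0.9, by = 0.2)
  for (poff in c(0.05, 0.2)) {
    p <- vapply(grid, p_decode, numeric(1), p_off = poff, n_con = 4, n_stim = 5)
    expect_true(all(diff(p) > 0))  # increasing in p_on
  }
  p_off_grid <- seq(0, 0.4, by = 0.1)
  p <- vapply(p_off_grid, function(q) p_decode(0.8, q, 4, 5), numeric(1))
  expect_true(all(diff(p) < 0))    # decreasing in p_off
  p_ncon <- vapply(1:6, function(nc) p_decode(0.6, 0.2, nc, 5), numeric(1))
  expect_true(all(diff(p_ncon) > 0))
  p_nstim <- vapply(2:6, function(ns) p_decode(0.6, 0.2, 4, ns), numeric(1))
  expect_true(all(diff(p_nstim) < 0))
})

test_that("95% isolines admit more p_off with more connections", {
  iso2 <- isoline_95(2, 5)
  iso8 <- isoline_95(8, 5)
  shared <- intersect(iso2$p_on, iso8$p_on)
  expect_gt(length(shared), 5)
  expect_true(all(iso8$p_off[match(shared, iso8$p_on)] >=
                  iso2$p_off[match(shared, iso2$p_on)]))
  # isoline endpoint at p_off = 0 agrees with a direct 1-D threshold search
  pon_min <- min(iso2$p_on)
  direct <- min(Filter(function(q) p_decode(q, 0, 2, 5) >= 0.95,
                       seq(0.01, 1, by = 0.01)))
  expect_equal(pon_min, direct)
})

test_that("coverage probability matches Monte Carlo and is monotone", {
  expect_equal(coverage_probability(c(0, 3, 10), 0, 5), c(0, 0, 0))
  expect_equal(coverage_probability(1, 1, 2), 1)
  expect_equal(coverage_probability(2, 1, 5), 0)  # k < n_stim - 1
  set.seed(21)
  for (k in c(5, 10, 20)) {
    p <- coverage_probability(k, 0.5, 5)
    phat <- mc_coverage(k, 0.5, 5, n_rep = 2e4)
    expect_lt(abs(p - phat), mc_tol(max(p, 0.02), 2e4))
  }
  ks <- 0:40
  pk <- coverage_probability(ks, 0.3, 5)
  expect_true(all(diff(pk) >= -1e-12))
  fs <- seq(0.1, 1, by = 0.1)
  pf <- vapply(fs, function(f) coverage_probability(12, f, 5), numeric(1))
  expect_true(all(diff(pf) >= -1e-12))
})

test_that("min_readouts behaves like the coupon-collector bound", {
  expect_equal(min_readouts(1, 2), 1)
  expect_identical(min_readouts(0, 5), Inf)
  fs <- c(0.1, 0.2, 0.5, 1)
  ks <- vapply(fs, min_readouts, numeric(1), n_stim = 5)
  expect_true(all(diff(ks) <= 0))  # non-increasing in f
  # definition: smallest k exceeding the certainty
  k5 <- min_readouts(0.5, 5)
  expect_gt(coverage_probability(k5, 0.5, 5), 0.95)
  expect_lte(coverage_probability(k5 - 1, 0.5, 5), 0.95)
})

test_that("fit_L recovers an exact 1/f law and grows with n_stim", {
  # synthetic k(f) = c/f must give L = c with zero residual
  f_grid <- c(0.1, 0.2, 0.4, 0.8)
  k_exact <- 24 / f_grid
  L <- mean(k_exact * f_grid)
  expect_equal(L, 24)
  expect_equal(max(abs(k_exact * f_grid - L) / L), 0)
  fits <- lapply(c(2, 3, 5), function(ns) fit_L(ns))
  Ls <- vapply(fits, `[[`, numeric(1), "L")
  expect_true(all(diff(Ls) > 0))
  # fitted constant stays close to the numeric minimal readouts on the grid
  f5 <- fits[[3]]
  expect_true(all(abs(f5$residual_rel) < 0.15))
})

test_that("energy model optimum matches numeric minimization and algebra", {
  L <- fit_L(5)$L
  N <- 1000; p_con <- 0.04; beta <- 40
  for (gamma in c(5, 20, 40)) {
    f_closed <- optimal_fraction(gamma, L, N, p_con, beta, clamp = FALSE)
    opt <- optimize(function(f) energy(f, gamma, L, N, p_con, beta),
                    interval = c(1e-4, 10), tol = 1e-10)
    expect_equal(f_closed, opt$minimum, tolerance = 1e-6)
  }
  # setting f_min = 1 recovers gamma_min = p_con * beta * N / L exactly
  gamma_min <- critical_ratio(L, N, p_con, beta)
  expect_equal(optimal_fraction(gamma_min, L, N, p_con, beta, clamp = FALSE), 1)
  expect_equal(gamma_min, p_con * beta * N / L)
  # E is convex on (0, 1]: midpoint below chord
  f <- c(0.2, 0.8); gamma <- 30
  E <- function(x) energy(x, gamma, L, N, p_con, beta)
  expect_lt(E(mean(f)), mean(E(f)))
  # n_SRC at f = 1 under the simulation geometry
  expect_equal(1 * N * p_con * beta, 1600)
})
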