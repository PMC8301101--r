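#' Analytic decoding probability for tuned Bernoulli populations
#'
#' Consider `n_stim` populations of `n_con` readout neurons each, every
#' neuron tuned to one stimulus: it spikes with probability `p_on` for its
#' preferred stimulus and `p_off` otherwise, independently. The decoder
#' outputs the stimulus whose population spiked most; ties are losses (the
#' correct population must fire strictly more). The success probability is
#'
#' \deqn{P = \sum_{k=1}^{n_{con}} \binom{n_{con}}{k} p_{on}^k (1-p_{on})^{n_{con}-k}
#'   \left[ P(\mathrm{Bin}(n_{con}, p_{off}) \le k-1) \right]^{n_{stim}-1}.}
#'
#' @param p_on,p_off response probabilities, `0 <= p_off <= p_on <= 1`.
#' @param n_con readout neurons per stimulus.
#' @param n_stim number of stimuli.
#' @return decoding probability.
#' @examples
#' p_decode(0.8, 0.1, n_con = 1, n_stim = 2)  # 0.8 * 0.9 = 0.72
#' @export
p_decode <- function(p_on, p_off, n_con, n_stim) {
  stopifnot(p_off >= 0, p_on <= 1, p_off <= p_on, n_con >= 1, n_stim >= 2)
  k <- seq_len(n_con)
  sum(dbinom(k, n_con, p_on) * pbinom(k - 1, n_con, p_off)^(n_stim - 1))
}

#' 95% decoding isolines in the (p_on, p_off) plane
#'
#' For each `p_on` on a grid, finds (by bisection) the largest `p_off` for
#' which the decoding probability still reaches `level`. Grid points whose
#' `p_on` cannot reach `level` even at `p_off = 0` are omitted.
#'
#' @param n_con readout neurons per stimulus.
#' @param n_stim number of stimuli.
#' @param p_on_grid grid of preferred-stimulus response probabilities.
#' @param level target decoding probability.
#' @param tol bisection tolerance on `p_off`.
#' @return data frame (`p_on`, `p_off`) tracing the isoline.
#' @export
isoline_95 <- function(n_con, n_stim, p_on_grid = seq(0.01, 1, by = 0.01),
                       level = 0.95, tol = 1e-6) {
  rows <- lapply(p_on_grid, function(pon) {
    if (p_decode(pon, 0, n_con, n_stim) < level) return(NULL)
    lo <- 0; hi <- pon
    if (p_decode(pon, hi, n_con, n_stim) >= level) {
      poff <- hi
    } else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (p_decode(pon, mid, n_con, n_stim) >= level) lo <- mid else hi <- mid
      }
      poff <- lo
    }
    data.frame(p_on = pon, p_off = poff)
  })
  do.call(rbind, rows)
}

# P(j uniform draws from n_stim categories cover at least n_stim - 1
# distinct categories), by inclusion-exclusion over exact coverage counts.
cover_at_least <- function(j, n_stim) {
  vapply(j, function(jj) {
    if (n_stim - 1 <= 0) return(1)
    tot <- 0
    for (r in (n_stim - 1):n_stim) {
      if (jj < r) next
      i <- 0:r
      tot <- tot + choose(n_stim, r) *
        sum((-1)^i * choose(r, i) * ((r - i) / n_stim)^jj)
    }
    min(max(tot, 0), 1)
  }, numeric(1))
}

#' Coverage probability of random readout draws
#'
#' A fraction `f` of the network's neurons is tuned, each to a uniformly
#' random one of `n_stim` stimuli; the rest are untuned. `coverage_probability`
#' is the probability that `k` random draws contain at least `n_stim - 1`
#' differently tuned neurons (enough to identify every stimulus): a binomial
#' mixture over the number of tuned draws combined with the
#' inclusion-exclusion coverage probability of uniform categories.
#'
#' @param k number of draws (vectorized).
#' @param f tuned fraction in `[0, 1]`.
#' @param n_stim number of stimuli.
#' @return probability (vector along `k`).
#' @export
coverage_probability <- function(k, f, n_stim) {
  stopifnot(all(k >= 0), f >= 0, f <= 1, n_stim >= 2)
  vapply(k, function(kk) {
    j <- 0:kk
    sum(dbinom(j, kk, f) * cover_at_least(j, n_stim))
  }, numeric(1))
}

#' Minimal number of readout draws for reliable coverage
#'
#' The smallest `k` with `coverage_probability(k, f, n_stim) > certainty`.
#'
#' @param f tuned fraction (> 0; `f = 0` returns `Inf`, unreachable).
#' @param n_stim number of stimuli.
#' @param certainty required coverage probability.
#' @param k_max search cap.
#' @return minimal `k` (integer), or `Inf` when unreachable.
#' @export
min_readouts <- function(f, n_stim, certainty = 0.95, k_max = 100000L) {
  if (f <= 0) return(Inf)
  k <- n_stim - 1L
  while (k <= k_max) {
    if (coverage_probability(k, f, n_stim) > certainty) return(k)
    k <- k + 1L
  }
  Inf
}

#' Fit the 1/f scaling constant of the minimal readout count
#'
#' The minimal readout count scales with the tuned fraction approximately as
#' `k(f) = L(n_stim) / f`. Fits the constant by least squares on
#' `k(f) * f` over a grid of tuned fractions (20 log-spaced points in
#' `[0.05, 1]` by default) and reports residuals.
#'
#' @param n_stim number of stimuli.
#' @param f_grid grid of tuned fractions.
#' @param certainty coverage certainty defining `k(f)`.
#' @return list with `L`, `f_grid`, `k` (minimal readouts per grid point),
#'   `residual_rel` (relative residuals of `k*f` around `L`) and
#'   `max_residual_rel`.
#' @export
fit_L <- function(n_stim, f_grid = exp(seq(log(0.05), log(1), length.out = 20)),
                  certainty = 0.95) {
  stopifnot(length(f_grid) >= 2, all(f_grid > 0), all(f_grid <= 1))
  k <- vapply(f_grid, min_readouts, numeric(1), n_stim = n_stim,
              certainty = certainty)
  y <- k * f_grid
  L <- mean(y)
  res <- (y - L) / L
  list(L = L, f_grid = f_grid, k = k, residual_rel = res,
       rms_residual_rel = sqrt(mean(res^2)),
       max_residual_rel = max(abs(res)))
}

#' Metabolic cost of the emergent architecture
#'
#' Relative cost of maintaining the connectivity needed to route `n_stim`
#' stimuli through a recurrent layer with tuned fraction `f`:
#' `E(f) = gamma * L / f + f * N * p_con * beta`, where `gamma` is the cost
#' of a long-range connection relative to a short-range one,
#' `n_LRC = L / f` the long-range readouts needed, and
#' `n_SRC = f * N * p_con * beta` the strong short-range connections a
#' tuned fraction `f` maintains.
#'
#' @param f tuned fraction (vectorized).
#' @param gamma long- vs short-range cost ratio.
#' @param L coverage constant `L(n_stim)` (from [fit_L()]).
#' @param N network size.
#' @param p_con connection probability.
#' @param beta stimulated neurons per stimulus.
#' @return relative cost (vector along `f`).
#' @export
energy <- function(f, gamma, L, N, p_con, beta) {
  stopifnot(all(f > 0), gamma > 0, L > 0, N > 0, p_con > 0, beta > 0)
  gamma * L / f + f * N * p_con * beta
}

#' Cost-optimal tuned fraction
#'
#' Setting `dE/df = 0` gives `f_min = sqrt(gamma * L / (N * p_con * beta))`;
#' when that exceeds 1, `E` is decreasing on `(0, 1]` and the fully tuned
#' network `f = 1` is optimal.
#'
#' @inheritParams energy
#' @param clamp clamp the optimum into `(0, 1]` (default `TRUE`).
#' @return optimal tuned fraction.
#' @export
optimal_fraction <- function(gamma, L, N, p_con, beta, clamp = TRUE) {
  f <- sqrt(gamma * L / (N * p_con * beta))
  if (clamp) min(f, 1) else f
}

#' Critical cost ratio for full tuning
#'
#' The smallest long/short-range cost ratio at which the fully tuned
#' network (`f = 1`) is the cost-optimal architecture:
#' `gamma_min = p_con * beta * N / L(n_stim)` (obtained by setting
#' `f_min = 1`).
#'
#' @inheritParams energy
#' @return critical ratio `gamma_min`.
#' @export
critical_ratio <- function(L, N, p_con, beta) {
  stopifnot(L > 0, N > 0, p_con > 0, beta > 0)
  p_con * beta * N / L
}
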