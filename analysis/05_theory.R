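#!/usr/bin/env Rscript
# Analytic models, no simulation required: decoding probability isolines,
# coverage/minimal-readout scaling with the tuned fraction, the L(n_stim)
# fit, and the metabolic-cost optimum. Writes results/theory/.
#
# Usage: Rscript analysis/05_theory.R

library(sornroute)

out_dir <- file.path("results", "theory")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# 95% isolines for 5 stimuli at several readouts-per-stimulus counts
iso <- do.call(rbind, lapply(c(1, 2, 4, 8, 16), function(nc) {
  data.frame(n_con = nc, isoline_95(nc, 5))
}))
write.table(iso, file.path(out_dir, "isolines_95.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# minimal readouts vs tuned fraction and the L/f fit, for 2..6 stimuli
fit_rows <- lapply(2:6, function(ns) {
  fit <- fit_L(ns)
  write.table(data.frame(n_stim = ns, f = fit$f_grid, k = fit$k,
                         L_over_f = fit$L / fit$f_grid),
              file.path(out_dir, sprintf("min_readouts_nstim%d.tsv", ns)),
              sep = "\t", quote = FALSE, row.names = FALSE, append = FALSE)
  data.frame(n_stim = ns, L = fit$L, max_rel_residual = fit$max_residual_rel)
})
fits <- do.call(rbind, fit_rows)
write.table(fits, file.path(out_dir, "L_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("L(n_stim) fits (minimal readouts ~ L/f):")
print(fits, row.names = FALSE)

# metabolic cost under the simulation geometry
N <- 1000; p_con <- 0.04; beta <- 40
cost_rows <- lapply(2:6, function(ns) {
  L <- fits$L[fits$n_stim == ns]
  data.frame(n_stim = ns, L = L,
             n_SRC_full = N * p_con * beta,
             gamma_min = critical_ratio(L, N, p_con, beta),
             f_min_gamma40 = optimal_fraction(40, L, N, p_con, beta))
})
cost <- do.call(rbind, cost_rows)
write.table(cost, file.path(out_dir, "metabolic_cost.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cost model (N = 1000, p_con = 0.04, beta = 40; 1600 short-range ",
        "connections at f = 1):")
print(cost, row.names = FALSE)
message("a fully tuned network is cost-optimal whenever the long/short ",
        "cost ratio exceeds gamma_min = p_con*beta*N/L(n_stim).")
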