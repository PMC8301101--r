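# sornroute

Self-organized routing of stimulus information in recurrent spiking
networks.

## The problem

Cortical layers are recurrent networks wired to each other by sparse,
random, developmentally fixed long-range connections. A stimulus therefore
arrives at a small random subset of a layer's neurons and must be decodable
by another small random subset that projects onward. `sornroute` implements
and analyzes a self-organizing recurrent network (SORN) model of how local
plasticity solves this routing problem: conductance-based leaky
integrate-and-fire neurons (1000 excitatory, 200 inhibitory, sparse random
connectivity `p = 0.04`) equipped with

* **STDP** on recurrent excitatory synapses,
  `dw = ±0.05 nS · exp(−|Δt|/20 ms)`,
* **synaptic normalization**, keeping each neuron's summed incoming
  excitatory weight at `W_total = 50 nS` (winner-take-all competition), and
* **intrinsic plasticity**, an adaptive firing threshold (decay 0.2 mV/s,
  +0.066 mV per spike) that homeostatically holds every neuron near
  0.2/0.066 ≈ 3 Hz.

Training drives five disjoint groups of 40 excitatory neurons through
strong (20 nS) input synapses from group-specific 50 Hz Poisson sources;
testing probes the network with single precisely timed input spikes and
reads out the binned spiking response in the first 2.5 ms. The package
also implements the accompanying analytic models: the decoding probability
of tuned Bernoulli populations

`P = Σ_k C(n_con,k) p_on^k (1−p_on)^(n_con−k) · [P(Bin(n_con, p_off) ≤ k−1)]^(n_stim−1)`,

the coverage probability that `k` random readouts contain at least
`n_stim − 1` distinct tunings (with its `L(n_stim)/f` scaling law), and the
metabolic cost model `E(f) = γ·L/f + f·N·p_con·β` with optimal tuned
fraction `f_min = sqrt(γL/(N·p_con·β))`.

## Worked example

```r
library(sornroute)

# analytic: information carried by a perfectly tuned cell (1 of 5 stimuli)
mutual_information(c(1, 0, 0, 0, 0), "paper_expression")
#> [1] 0.4643856
mutual_information(c(1, 0, 0, 0, 0))   # full binary entropy H2(0.2)
#> [1] 0.7219281

# analytic: readout coverage scaling and wiring cost
fit <- fit_L(5)          # minimal readouts ~ L/f
round(fit$L, 2)
#> [1] 12.23
round(critical_ratio(fit$L, N = 1000, p_con = 0.04, beta = 40), 1)
#> [1] 130.8  # cost ratio above which full tuning (f = 1) is optimal

# simulate the scaled-down protocol (300 E / 60 I, 3 stimuli of 20), then
# extract tuning and decode; ~3-4 min per run
cfg <- scaled_config(training_s = 96)
run <- run_protocol(build_network(cfg, seed = 1), seed = 2)
resp <- extract_responses(run$spikes$testing, run$cue_log,
                          n_neurons = cfg$network$n_E)
prof <- tuning_profile(resp)
round(prof$fractions, 2)   # fraction of neurons with 0,1,2,3 tunings
#>    0    1    2    3
#> 0.17 0.73 0.10 0.00
round(median(prof$mi), 2)  # per-cell stimulus information (bit)
#> [1] 0.32
```

After training, most neurons respond rapidly to exactly one stimulus
(the single-tuned information reference is H2(1/3) = 0.92 bit for three
stimuli; seeds vary in how far the median climbs towards it). One major
caveat is documented in the
methods vignette and the test suite: with this equation set the
stimulus-to-stimulus competition is unstable — a single stimulated group's
assembly tends to capture the whole reservoir instead of the network
partitioning into per-stimulus sub-networks — so the trained network's
sparse-readout improvement is not reproduced, and the acceptance checks
covering it fail openly rather than being relaxed. The vignette analyzes
the mechanism and the model variants explored.

The numbered drivers under `analysis/` run the full workflow and write
tidy tables under `results/`: `01_simulate.R` (protocol sweep over
training times), `02_tuning.R` (response probabilities, tunings, mutual
information), `03_decode.R` (accuracy vs readout count, minimal readouts
per classifier), `04_weights.R` (connection-class histograms, block
structure, correlation-sorted weight curves), `05_theory.R` (isolines,
`L(n_stim)` fits, metabolic cost).

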