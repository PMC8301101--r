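# Thin R wrappers around the clock-driven C++ core.

# split synapse table into class-wise 0-based edge arrays for the core
edge_arrays <- function(synapses) {
  cls <- synapses$class
  out <- list()
  for (k in c("EE", "EI", "IE")) {
    sel <- cls == k
    out[[k]] <- list(pre = as.integer(synapses$pre[sel] - 1L),
                     post = as.integer(synapses$post[sel] - 1L),
                     w = as.numeric(synapses$weight[sel]))
  }
  out
}

#' Simulate one protocol phase
#'
#' Advances the network for `duration_ms` with forward-Euler integration at
#' time step `dt` (default 0.1 ms). Plasticity switches select the phase
#' semantics: STDP plus normalization (`stdp_on`), intrinsic threshold
#' plasticity (`ip_on`), and the Ornstein-Uhlenbeck membrane noise
#' (`noise_on`). External input spikes, if any, are delivered through fixed
#' `input_weight` conductance synapses to every member of the addressed
#' stimulation group.
#'
#' Uses R's random number stream (seed with [set.seed()] before calling for
#' reproducibility).
#'
#' @param network `sorn_network` object.
#' @param duration_ms phase duration in ms.
#' @param stdp_on,ip_on,noise_on plasticity/noise switches.
#' @param ext_spikes `NULL` or data frame (`time_ms`, `group`) of input
#'   spike events, times relative to the current network clock, sorted.
#' @param groups list of stimulation-group member id vectors (1-based).
#' @param input_weight input synapse conductance in nS.
#' @param dt integration step in ms.
#' @return list with the updated `network` and `spikes`, a data frame
#'   (`time_ms`, `neuron`) of emitted spikes (absolute times).
#' @export
simulate_phase <- function(network, duration_ms, stdp_on = TRUE, ip_on = TRUE,
                           noise_on = TRUE, ext_spikes = NULL, groups = NULL,
                           input_weight = 20, dt = network$config$dt) {
  stopifnot(inherits(network, "sorn_network"), duration_ms >= 0, dt > 0)
  ea <- edge_arrays(network$synapses)
  if (is.null(ext_spikes) || nrow(ext_spikes) == 0L) {
    et <- numeric(0); eg <- integer(0)
  } else {
    o <- order(ext_spikes$time_ms)
    et <- as.numeric(ext_spikes$time_ms[o] + network$state$t_ms)
    eg <- as.integer(ext_spikes$group[o] - 1L)
  }
  if (is.null(groups)) groups <- list()
  gm <- lapply(groups, function(g) as.integer(g - 1L))
  res <- cpp_sim_phase(network$state, sim_params(network$config),
                       ea$EE$pre, ea$EE$post, ea$EE$w,
                       ea$EI$pre, ea$EI$post, ea$EI$w,
                       ea$IE$pre, ea$IE$post, ea$IE$w,
                       duration_ms, dt, stdp_on, ip_on, noise_on,
                       et, eg, gm, input_weight)
  network$state <- res$state
  network$synapses$weight[network$synapses$class == "EE"] <- res$ee_w
  list(network = network,
       spikes = data.frame(time_ms = res$spike_time,
                           neuron = res$spike_id + 1L))
}

# Poisson input schedule for the training phase: in each cycle_ms window,
# one group is active for active_ms with probability p_active (1 = every
# cycle); the active group is drawn uniformly with a no-immediate-repeat
# rule over consecutive active cycles; one shared Poisson train per group
# fans out to all members.
training_input <- function(duration_ms, n_stim, rate_hz, cycle_ms, active_ms,
                           p_active = 1, order = c("roundrobin", "random")) {
  order <- match.arg(order)
  n_cycles <- floor(duration_ms / cycle_ms)
  if (n_cycles == 0L)
    return(list(spikes = data.frame(time_ms = numeric(0), group = integer(0)),
                active = integer(0)))
  is_active <- runif(n_cycles) < p_active
  active <- integer(n_cycles)  # 0 = silent cycle
  if (order == "roundrobin") {
    # cyclic order keeps group exposure exactly balanced, which prevents
    # random early imbalances from being amplified by the STDP/normalization
    # positive feedback into a single dominant assembly
    active[is_active] <- rep_len(seq_len(n_stim), sum(is_active))
  } else {
    prev <- 0L
    for (i in seq_len(n_cycles)) {
      if (!is_active[i]) next
      cand <- if (n_stim > 1L && prev > 0L) setdiff(seq_len(n_stim), prev)
              else seq_len(n_stim)
      active[i] <- cand[sample.int(length(cand), 1L)]
      prev <- active[i]
    }
  }
  counts <- ifelse(active > 0L, rpois(n_cycles, rate_hz * active_ms / 1000), 0L)
  times <- lapply(which(counts > 0L), function(i) {
    sort(runif(counts[i], min = (i - 1) * cycle_ms,
               max = (i - 1) * cycle_ms + active_ms))
  })
  sp <- data.frame(time_ms = unlist(times),
                   group = rep(active[counts > 0L], counts[counts > 0L]))
  list(spikes = sp[order(sp$time_ms), , drop = FALSE], active = active)
}

# Independent-train variant: every member of the active group gets its own
# Poisson train (targets are singleton "groups", one per stimulated neuron;
# the returned group column indexes `members`).
training_input_independent <- function(duration_ms, n_stim, rate_hz, cycle_ms,
                                       active_ms, p_active, group_sizes) {
  base <- training_input(duration_ms, n_stim, rate_hz, cycle_ms, active_ms,
                         p_active)
  active <- base$active
  member_offset <- c(0L, cumsum(group_sizes))
  rows <- lapply(which(active > 0L), function(i) {
    g <- active[i]
    n_mem <- group_sizes[g]
    counts <- rpois(n_mem, rate_hz * active_ms / 1000)
    data.frame(
      time_ms = runif(sum(counts), min = (i - 1) * cycle_ms,
                      max = (i - 1) * cycle_ms + active_ms),
      group = rep(member_offset[g] + seq_len(n_mem), counts))
  })
  sp <- do.call(rbind, rows)
  if (is.null(sp)) sp <- data.frame(time_ms = numeric(0), group = integer(0))
  list(spikes = sp[order(sp$time_ms), , drop = FALSE], active = active)
}

# Balanced round-robin recall-cue log for the testing phase.
recall_cues <- function(duration_ms, n_stim, period_ms, offset_ms = period_ms / 2) {
  times <- seq(offset_ms, duration_ms - 1e-9, by = period_ms)
  data.frame(time_ms = times,
             stimulus = rep_len(seq_len(n_stim), length(times)))
}

#' Run the four-phase stimulation protocol
#'
#' Executes warm-up (plasticity on, no input), training (one group-specific
#' 50 Hz Poisson source active for 100 ms in every 200 ms cycle), relaxation
#' (STDP and inputs off, intrinsic plasticity re-equilibrates) and testing
#' (all plasticity frozen; one precisely timed input spike to all members of
#' one group every 500 ms, balanced round-robin over stimuli).
#'
#' @param network `sorn_network` from [build_network()].
#' @param seed integer seed for all protocol randomness (Poisson trains, OU
#'   noise).
#' @param snapshot_times_s optional training times (s) at which additional
#'   EE weight snapshots are taken.
#' @return list of class `sorn_run`: `spikes` (per-phase list of spike data
#'   frames), `snapshots` (named list of EE synapse tables; always includes
#'   phase boundaries), `cue_log` (recall times, absolute ms, and stimulus
#'   ids), `groups`, final `network`, `config`.
#' @export
run_protocol <- function(network, seed = 1L, snapshot_times_s = NULL) {
  cfg <- network$config
  pr <- cfg$protocol
  groups <- stimulus_groups(cfg)
  if (pr$n_stim * pr$beta > cfg$network$n_E)
    stop("stimulation groups do not fit into the excitatory population")
  if (anyDuplicated(unlist(groups)))
    stop("stimulus groups overlap")
  set.seed(seed)
  ee_snap <- function(net) {
    s <- net$synapses[net$synapses$class == "EE", c("pre", "post", "weight")]
    rownames(s) <- NULL
    s
  }
  spikes <- list(); snapshots <- list()

  ph <- simulate_phase(network, pr$warmup_s * 1000,
                       stdp_on = TRUE, ip_on = TRUE, noise_on = TRUE)
  network <- ph$network; spikes$warmup <- ph$spikes
  snapshots[["train_0s"]] <- ee_snap(network)

  snap_at <- sort(unique(snapshot_times_s))
  snap_at <- snap_at[snap_at > 0 & snap_at < pr$training_s]
  seg_bounds <- c(0, snap_at, pr$training_s)
  if (pr$training_s > 0) {
    shared <- isTRUE(pr$shared_poisson)
    if (shared) {
      inp <- training_input(pr$training_s * 1000, pr$n_stim, pr$poisson_rate,
                            pr$cycle_ms, pr$active_ms,
                            p_active = pr$p_cycle_active,
                            order = pr$training_order)
      input_groups <- groups
    } else {
      inp <- training_input_independent(pr$training_s * 1000, pr$n_stim,
                                        pr$poisson_rate, pr$cycle_ms,
                                        pr$active_ms, pr$p_cycle_active,
                                        lengths(groups))
      input_groups <- as.list(unlist(groups))
    }
    tr_spikes <- list()
    for (i in seq_len(length(seg_bounds) - 1L)) {
      lo <- seg_bounds[i] * 1000; hi <- seg_bounds[i + 1L] * 1000
      seg <- inp$spikes[inp$spikes$time_ms >= lo & inp$spikes$time_ms < hi, ]
      seg$time_ms <- seg$time_ms - lo
      ph <- simulate_phase(network, hi - lo, stdp_on = TRUE, ip_on = TRUE,
                           noise_on = TRUE, ext_spikes = seg,
                           groups = input_groups,
                           input_weight = pr$input_weight)
      network <- ph$network; tr_spikes[[i]] <- ph$spikes
      if (i < length(seg_bounds) - 1L)
        snapshots[[sprintf("train_%gs", seg_bounds[i + 1L])]] <- ee_snap(network)
    }
    spikes$training <- do.call(rbind, tr_spikes)
  } else {
    spikes$training <- data.frame(time_ms = numeric(0), neuron = integer(0))
  }
  snapshots[[sprintf("train_%gs", pr$training_s)]] <- ee_snap(network)

  ph <- simulate_phase(network, pr$relaxation_s * 1000,
                       stdp_on = FALSE, ip_on = TRUE, noise_on = TRUE)
  network <- ph$network; spikes$relaxation <- ph$spikes
  snapshots[["pre_test"]] <- ee_snap(network)

  cues <- recall_cues(pr$testing_s * 1000, pr$n_stim, pr$recall_period_ms)
  cue_abs <- cues
  cue_abs$time_ms <- cue_abs$time_ms + network$state$t_ms
  ph <- simulate_phase(network, pr$testing_s * 1000,
                       stdp_on = FALSE, ip_on = FALSE, noise_on = TRUE,
                       ext_spikes = data.frame(time_ms = cues$time_ms,
                                               group = cues$stimulus),
                       groups = groups, input_weight = pr$input_weight)
  network <- ph$network; spikes$testing <- ph$spikes
  snapshots[["post_test"]] <- ee_snap(network)

  structure(list(spikes = spikes, snapshots = snapshots, cue_log = cue_abs,
                 groups = groups, network = network, config = cfg,
                 seed = seed),
            class = "sorn_run")
}

#' Fresh simulations across training durations
#'
#' Runs a separate simulation for every requested training time, each a
#' fresh build-and-run from the same seed (not a continuation), so runs
#' share the network realization and warm-up but diverge in training.
#'
#' @param cfg configuration list; its `training_s` entry is overridden.
#' @param training_times_s numeric vector of training durations (s).
#' @param seed master seed used for every run.
#' @return named list of `sorn_run` objects (names `"t<seconds>"`).
#' @export
training_time_sweep <- function(cfg, training_times_s, seed = 1L) {
  stopifnot(length(training_times_s) >= 1)
  out <- lapply(training_times_s, function(ts) {
    cfg$protocol$training_s <- ts
    net <- build_network(cfg, seed = seed)
    run_protocol(net, seed = seed + 1L)
  })
  names(out) <- sprintf("t%g", training_times_s)
  out
}
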