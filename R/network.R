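#' Build a random sparse SORN network
#'
#' Draws the recurrent connectivity: every ordered excitatory pair (no
#' self-connections), every E-to-I pair and every I-to-E pair is connected
#' independently with probability `p_connect`; recurrent I-to-I connections
#' are absent. Recurrent E-to-E synapses start at `w_ee_init` (0.5 nS) and
#' are the only plastic ones; E-to-I and I-to-E start at `w_other_init`
#' (1 nS) and stay fixed.
#'
#' Neuron ids are 1..n_E (excitatory) followed by n_E+1..n_E+n_I
#' (inhibitory). The adaptive firing threshold starts at `v_th_init` for
#' every neuron; the warm-up phase lets intrinsic plasticity equilibrate it,
#' making results insensitive to the initial value.
#'
#' @param cfg configuration list from [default_config()].
#' @param seed integer seed; two builds with the same seed are identical.
#' @return An object of class `sorn_network`: list with `state` (membrane
#'   voltages, conductances, thresholds, refractory clocks, OU noise,
#'   last-spike times, clock), `synapses` (data frame `pre`, `post`,
#'   `weight`, `class` with class one of `"EE"`, `"EI"`, `"IE"`), and the
#'   configuration.
#' @export
build_network <- function(cfg = default_config(), seed = 1L) {
  rep <- validate_config(cfg)
  if (any(rep$level == "error"))
    stop("invalid configuration: ",
         paste(rep$message[rep$level == "error"], collapse = "; "))
  n_E <- cfg$network$n_E; n_I <- cfg$network$n_I
  p <- cfg$network$p_connect
  set.seed(seed)

  draw_pairs <- function(n_pre, n_post, pre_offset, post_offset, no_self) {
    # vectorized Bernoulli draw over the full ordered-pair grid
    m <- matrix(runif(n_pre * n_post) < p, n_pre, n_post)
    if (no_self) diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    data.frame(pre = idx[, 1] + pre_offset, post = idx[, 2] + post_offset)
  }

  ee <- draw_pairs(n_E, n_E, 0L, 0L, no_self = TRUE)
  ei <- draw_pairs(n_E, n_I, 0L, n_E, no_self = FALSE)
  ie <- draw_pairs(n_I, n_E, n_E, 0L, no_self = FALSE)
  with_cols <- function(df, w, cl) {
    df$weight <- rep(w, nrow(df)); df$class <- rep(cl, nrow(df)); df
  }
  syn <- rbind(with_cols(ee, cfg$network$w_ee_init, "EE"),
               with_cols(ei, cfg$network$w_other_init, "EI"),
               with_cols(ie, cfg$network$w_other_init, "IE"))
  syn <- syn[order(syn$pre, syn$post), , drop = FALSE]
  rownames(syn) <- NULL

  n <- n_E + n_I
  state <- list(
    v = rep(cfg$neuron$v_rest, n),
    g_ampa = numeric(n), g_gaba = numeric(n),
    v_th = c(rep(cfg$neuron$v_th_init, n_E),
             rep(cfg$neuron$v_th_inh, n_I)),
    refrac = numeric(n), xi = numeric(n),
    last_spike = rep(-1e30, n), t_ms = 0,
    n_exc = n_E, n_inh = n_I
  )
  structure(list(state = state, synapses = syn, config = cfg),
            class = "sorn_network")
}

#' @export
print.sorn_network <- function(x, ...) {
  cat("<sorn_network> ", x$state$n_exc, " excitatory + ", x$state$n_inh,
      " inhibitory neurons\n", sep = "")
  cat("  synapses:", paste(sprintf("%s=%d", names(table(x$synapses$class)),
                                   as.integer(table(x$synapses$class))),
                           collapse = ", "), "\n")
  cat("  clock:", x$state$t_ms, "ms\n")
  invisible(x)
}

#' Stimulation groups
#'
#' The `n_stim` disjoint stimulation groups of `beta` excitatory neurons
#' each, taken as consecutive id blocks at the start of the excitatory
#' population (ids 1..n_stim*beta).
#'
#' @param cfg configuration list.
#' @return list of integer vectors, one per stimulus.
#' @export
stimulus_groups <- function(cfg) {
  n_stim <- cfg$protocol$n_stim; beta <- cfg$protocol$beta
  lapply(seq_len(n_stim), function(s) ((s - 1L) * beta + 1L):(s * beta))
}
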