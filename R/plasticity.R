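#' STDP weight change for a spike-time difference
#'
#' Exponential spike-timing-dependent plasticity kernel. With
#' `delta_t = t_post - t_pre`, causal pairings (`delta_t > 0`) potentiate by
#' `A_plus * exp(-delta_t / tau_plus)`, anti-causal pairings depress by
#' `A_minus * exp(delta_t / tau_minus)`, and coincident spikes
#' (`delta_t = 0`) leave the weight unchanged.
#'
#' @param delta_t spike-time difference(s) t_post - t_pre in ms (vectorized).
#' @param plasticity list with `A_plus`, `A_minus`, `tau_plus`, `tau_minus`
#'   (see [default_config()]).
#' @return weight change(s) in nS; positive = potentiation.
#' @examples
#' stdp_delta(20, default_config()$plasticity)   # +0.05 * exp(-1)
#' stdp_delta(-20, default_config()$plasticity)  # -0.05 * exp(-1)
#' @export
stdp_delta <- function(delta_t, plasticity = default_config()$plasticity) {
  stopifnot(all(is.finite(delta_t)))
  ifelse(delta_t > 0, plasticity$A_plus * exp(-delta_t / plasticity$tau_plus),
         ifelse(delta_t < 0, -plasticity$A_minus * exp(delta_t / plasticity$tau_minus),
                0))
}

#' Synaptic normalization of incoming plastic weights
#'
#' Multiplicatively rescales the incoming E-to-E weight vector of one
#' postsynaptic neuron so that its L1 norm equals `W_total`, preserving
#' relative proportions. In the simulation this runs after every
#' STDP-induced change, so the summed incoming excitatory weight of every
#' excitatory neuron is conserved at `W_total`.
#'
#' @param synapses synapse data frame (`pre`, `post`, `weight`, `class`).
#' @param post_neuron id of the postsynaptic neuron.
#' @param W_total target L1 norm in nS.
#' @return synapse data frame with rescaled incoming EE weights.
#' @export
normalize_incoming <- function(synapses, post_neuron, W_total = 50) {
  sel <- synapses$class == "EE" & synapses$post == post_neuron
  if (!any(sel)) stop("neuron ", post_neuron, " has no incoming plastic EE synapse")
  s <- sum(synapses$weight[sel])
  if (s == 0)
    stop("degenerate normalization: all incoming EE weights of neuron ",
         post_neuron, " are zero")
  synapses$weight[sel] <- synapses$weight[sel] * (W_total / s)
  synapses
}
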