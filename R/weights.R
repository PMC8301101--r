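# Analyses of the emergent excitatory weight structure.

#' Classify recurrent excitatory connections by stimulation-group membership
#'
#' Labels every E-to-E synapse by its endpoints' stimulation-group
#' membership: `intra_stimulus` (both in the same group), `inter_stimulus`
#' (both stimulated, different groups), `stim_to_reservoir` (stimulated
#' presynaptic, unstimulated postsynaptic), `reservoir_to_stim` (the
#' converse) and `reservoir` (both unstimulated). The labels partition the
#' EE synapses.
#'
#' @param synapses synapse data frame; only rows with `class == "EE"` (or a
#'   frame without a `class` column, treated as all-EE) are labelled.
#' @param groups list of stimulation-group member vectors.
#' @return the EE synapse data frame with an added `conn_class` factor.
#' @export
classify_connections <- function(synapses, groups) {
  if (anyDuplicated(unlist(groups))) stop("a neuron belongs to two stimulus groups")
  if ("class" %in% names(synapses))
    synapses <- synapses[synapses$class == "EE", , drop = FALSE]
  memb <- integer(0)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  gid <- function(id) {
    out <- rep(NA_integer_, length(id))
    in_tab <- id <= length(memb)
    out[in_tab] <- memb[id[in_tab]]
    out
  }
  gp <- gid(synapses$pre); gq <- gid(synapses$post)
  lab <- ifelse(!is.na(gp) & !is.na(gq) & gp == gq, "intra_stimulus",
         ifelse(!is.na(gp) & !is.na(gq), "inter_stimulus",
         ifelse(!is.na(gp), "stim_to_reservoir",
         ifelse(!is.na(gq), "reservoir_to_stim", "reservoir"))))
  synapses$conn_class <- factor(lab, levels = c("intra_stimulus",
    "inter_stimulus", "stim_to_reservoir", "reservoir_to_stim", "reservoir"))
  rownames(synapses) <- NULL
  synapses
}

#' Tidy per-class weight table over training snapshots
#'
#' Stacks classified EE weights across weight snapshots into one tidy table
#' for histograms / class-mean comparisons over training time.
#'
#' @param snapshots named list of EE synapse tables (e.g. the `snapshots`
#'   element of a `sorn_run`).
#' @param groups stimulation groups.
#' @return data frame (`snapshot`, `conn_class`, `weight`).
#' @export
weight_class_table <- function(snapshots, groups) {
  rows <- lapply(names(snapshots), function(nm) {
    lab <- classify_connections(snapshots[[nm]], groups)
    data.frame(snapshot = nm, conn_class = lab$conn_class, weight = lab$weight)
  })
  do.call(rbind, rows)
}

#' Resort neurons by dominant input group
#'
#' Orders the excitatory neurons by the stimulation group from which they
#' receive the largest summed EE weight, and within a group by decreasing
#' size of that weight — the ordering under which a successfully trained
#' network's weight matrix becomes block-diagonal.
#'
#' @param synapses EE synapse table (`pre`, `post`, `weight`).
#' @param groups stimulation groups.
#' @param n_exc number of excitatory neurons.
#' @return list with `order` (permutation of `1..n_exc`), `block` (dominant
#'   group per neuron) and `input_weight` (summed weight from that group).
#' @export
resort_matrix <- function(synapses, groups, n_exc) {
  if ("class" %in% names(synapses))
    synapses <- synapses[synapses$class == "EE", , drop = FALSE]
  n_g <- length(groups)
  w_from <- matrix(0, n_exc, n_g)
  for (g in seq_len(n_g)) {
    sel <- synapses$pre %in% groups[[g]]
    if (any(sel)) {
      agg <- tapply(synapses$weight[sel], synapses$post[sel], sum)
      w_from[as.integer(names(agg)), g] <- agg
    }
  }
  block <- max.col(w_from, ties.method = "first")
  iw <- w_from[cbind(seq_len(n_exc), block)]
  ord <- order(block, -iw, seq_len(n_exc))
  list(order = ord, block = block, input_weight = iw)
}

#' Within- vs between-block mean weight ratio
#'
#' Mean weight of EE synapses connecting neurons assigned to the same
#' dominant input group, divided by the mean weight of synapses crossing
#' blocks. Near 1 for an untrained network; well above 1 once training has
#' carved the block-diagonal structure.
#'
#' @param synapses EE synapse table.
#' @param block per-neuron block assignment (from [resort_matrix()]).
#' @return ratio (numeric).
#' @export
block_weight_ratio <- function(synapses, block) {
  if ("class" %in% names(synapses))
    synapses <- synapses[synapses$class == "EE", , drop = FALSE]
  same <- block[synapses$pre] == block[synapses$post]
  mean(synapses$weight[same]) / mean(synapses$weight[!same])
}

#' Pairwise mean input weights from two stimulation groups
#'
#' For every excitatory neuron, the mean incoming EE weight from the
#' members of group `a` and from group `b` (0 when no such synapse exists),
#' with their correlation: after winner-take-all self-organization, neurons
#' with strong input from one group have weak input from the other, making
#' the correlation negative.
#'
#' @param synapses EE synapse table.
#' @param group_a,group_b member id vectors (disjoint).
#' @param n_exc number of excitatory neurons.
#' @return list with `table` (`neuron`, `mean_a`, `mean_b`) and
#'   `correlation` (Pearson, neurons outside both groups).
#' @export
pairwise_group_weights <- function(synapses, group_a, group_b, n_exc) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if ("class" %in% names(synapses))
    synapses <- synapses[synapses$class == "EE", , drop = FALSE]
  mean_from <- function(members) {
    out <- numeric(n_exc)
    sel <- synapses$pre %in% members
    if (any(sel)) {
      agg <- tapply(synapses$weight[sel], synapses$post[sel], mean)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  tab <- data.frame(neuron = seq_len(n_exc),
                    mean_a = mean_from(group_a), mean_b = mean_from(group_b))
  outside <- setdiff(seq_len(n_exc), c(group_a, group_b))
  r <- if (length(outside) > 2 &&
           sd(tab$mean_a[outside]) > 0 && sd(tab$mean_b[outside]) > 0)
    cor(tab$mean_a[outside], tab$mean_b[outside]) else NA_real_
  list(table = tab, correlation = r)
}

#' Cumulative weight and count curves over response correlation
#'
#' For every EE synapse, computes the Pearson correlation between the
#' binary post-cue response indicators of its pre- and postsynaptic neurons
#' across test trials (first 2.5 ms only), sorts synapses by ascending
#' correlation and accumulates weight and connection-count fractions. After
#' self-organization most synaptic weight sits on the most correlated
#' pairs, so the weight curve lags far behind the count curve.
#'
#' Pairs with a zero-variance response vector have undefined correlation;
#' they are kept at correlation 0 (with a warning) so the curves retain
#' full support.
#'
#' @param responses `response_table` covering all excitatory neurons.
#' @param synapses EE synapse table.
#' @return list with `curve` (data frame `correlation`, `cum_weight_frac`,
#'   `cum_count_frac`), `corr_at_half_weight` (correlation where the weight
#'   curve crosses 1/2) and `top_connection_frac` (fraction of connections,
#'   taken from the most-correlated end, holding half the total weight).
#' @export
correlation_weight_curve <- function(responses, synapses) {
  if ("class" %in% names(synapses))
    synapses <- synapses[synapses$class == "EE", , drop = FALSE]
  ind <- responses$indicator
  C <- suppressWarnings(cor(ind))
  rho <- C[cbind(synapses$pre, synapses$post)]
  n_undef <- sum(is.na(rho))
  if (n_undef > 0) {
    warning(n_undef, " synapse(s) with zero-variance responses; correlation set to 0")
    rho[is.na(rho)] <- 0
  }
  o <- order(rho)
  w <- synapses$weight[o]
  curve <- data.frame(correlation = rho[o],
                      cum_weight_frac = cumsum(w) / sum(w),
                      cum_count_frac = seq_along(w) / length(w))
  i_half <- which(curve$cum_weight_frac >= 0.5)[1]
  list(curve = curve,
       corr_at_half_weight = curve$correlation[i_half],
       top_connection_frac = 1 - curve$cum_count_frac[i_half])
}
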