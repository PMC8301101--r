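# Stimulus decoding from random readout subsets.

# trials x (5 * |subset|) feature matrix: binned spike counts of the
# subset's neurons within the post-cue window
response_features <- function(responses, subset) {
  d <- dim(responses$counts)
  matrix(responses$counts[, subset, , drop = FALSE],
         nrow = d[1], ncol = length(subset) * d[3])
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

fit_and_score <- function(X_tr, y_tr, X_te, y_te, classifier, epochs = 30L) {
  pred <- switch(classifier,
    perceptron = {
      lev <- sort(unique(y_tr))
      W <- cpp_perceptron_fit(X_tr, match(y_tr, lev) - 1L, length(lev), epochs)
      scores <- cbind(1, X_te) %*% W
      lev[max.col(scores, ties.method = "first")]
    },
    svm = {
      fit <- e1071::svm(X_tr, factor(y_tr), kernel = "linear", scale = FALSE)
      as.integer(as.character(predict(fit, X_te)))
    },
    knn3 = as.integer(as.character(class::knn(X_tr, X_te, factor(y_tr), k = 3))),
    stop("unknown classifier '", classifier, "' (use perceptron, svm or knn3)")
  )
  mean(pred == y_te)
}

# stratified n_folds-CV accuracy of one neuron subset (mean over folds)
subset_cv_accuracy <- function(responses, subset, classifier, n_folds = 5L) {
  X <- response_features(responses, subset)
  y <- responses$stimulus
  fold <- stratified_folds(y, n_folds)
  accs <- vapply(seq_len(n_folds), function(fo) {
    te <- fold == fo
    fit_and_score(X[!te, , drop = FALSE], y[!te],
                  X[te, , drop = FALSE], y[te], classifier)
  }, numeric(1))
  accs
}

#' Decoding accuracy from random readout subsets
#'
#' Repeatedly selects `n_subsets` random subsets of `subset_size` neurons,
#' takes their binned post-cue spike counts as features, and scores a
#' classifier under stratified `n_folds`-fold cross-validation (each fold's
#' held-out 20% tested once, i.e. the standard 80/20 stratified scheme).
#'
#' @param responses `response_table`.
#' @param subset_size number of readout neurons.
#' @param classifier `"perceptron"`, `"svm"` (linear kernel) or `"knn3"`
#'   (k-nearest neighbours, k = 3).
#' @param n_subsets random subset draws.
#' @param n_folds cross-validation folds.
#' @param seed integer seed.
#' @return list with `mean`, `sd` (over folds x subsets) and `accuracies`.
#' @export
decode_accuracy <- function(responses, subset_size, classifier = "perceptron",
                            n_subsets = 6L, n_folds = 5L, seed = 1L) {
  n_neurons <- ncol(responses$indicator)
  stopifnot(subset_size >= 1, subset_size <= n_neurons)
  set.seed(seed)
  accs <- unlist(lapply(seq_len(n_subsets), function(s) {
    subset <- sample.int(n_neurons, subset_size)
    subset_cv_accuracy(responses, subset, classifier, n_folds)
  }))
  list(mean = mean(accs), sd = sd(accs), accuracies = accs)
}

#' Minimal readout count for a target decoding accuracy
#'
#' For each of `n_sequences` random decreasing sequences, starts from
#' `start_size` readout neurons (which must decode above `threshold`),
#' removes one random neuron at a time (nested subsets) and re-evaluates the
#' cross-validated accuracy until it first drops below `threshold`; the last
#' subset size at or above threshold is recorded. Returns the mean and sd of
#' that size over sequences.
#'
#' @param responses `response_table`.
#' @param classifier classifier name (see [decode_accuracy()]).
#' @param threshold accuracy threshold in (0, 1).
#' @param n_sequences number of decreasing sequences.
#' @param start_size initial subset size (default: all neurons).
#' @param n_folds cross-validation folds.
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `sizes` (per sequence; `NA` when the
#'   starting subset already fails the threshold, i.e. not reachable) and
#'   `reachable`.
#' @export
minimal_readout <- function(responses, classifier = "perceptron",
                            threshold = 0.95, n_sequences = 40L,
                            start_size = NULL, n_folds = 5L, seed = 1L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n_neurons <- ncol(responses$indicator)
  if (is.null(start_size)) start_size <- n_neurons
  stopifnot(start_size >= 1, start_size <= n_neurons)
  set.seed(seed)
  sizes <- vapply(seq_len(n_sequences), function(sq) {
    subset <- sample.int(n_neurons, start_size)
    acc <- mean(subset_cv_accuracy(responses, subset, classifier, n_folds))
    if (acc < threshold) return(NA_real_)
    last_ok <- length(subset)
    while (length(subset) > 1L) {
      subset <- subset[-sample.int(length(subset), 1L)]
      acc <- mean(subset_cv_accuracy(responses, subset, classifier, n_folds))
      if (acc < threshold) return(last_ok)
      last_ok <- length(subset)
    }
    last_ok
  }, numeric(1))
  list(mean = mean(sizes, na.rm = TRUE),
       sd = sd(sizes, na.rm = TRUE),
       sizes = sizes, reachable = !all(is.na(sizes)))
}
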