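# Multi-label classifier retraining for limited-label (weak-label) data.
# After full two-phase training, each function's classifier is retrained
# alone on a class-rebalanced bootstrap of the training set, with the
# embedding modules and every other classifier frozen. Rebalancing uses
# square-root sampling: the probability of drawing class j is
# sqrt(n_j) / (sqrt(n_j) + sqrt(N - n_j)) — a compromise between the natural
# class frequencies and a fully balanced draw that softens the long tail
# without over-amplifying rare (and possibly mislabeled) positives.

#' Square-root sampling probabilities
#'
#' For a function with `n_pos` positives among `N` training samples, the
#' probability of drawing the positive class is
#' `sqrt(n_pos) / (sqrt(n_pos) + sqrt(N - n_pos))`; the negative-class
#' probability is its complement (the same formula applied to
#' `n_neg = N - n_pos`), so the two always sum to exactly 1.
#'
#' @param n_pos Number of positive samples (0 <= n_pos <= N).
#' @param N Total number of training samples (N >= 1).
#' @return A list with `p_positive` and `p_negative`.
#' @export
sampling_probability <- function(n_pos, N) {
  if (N < 1) stop("N must be >= 1")
  if (n_pos < 0 || n_pos > N) stop("n_pos must be between 0 and N")
  p_pos <- sqrt(n_pos) / (sqrt(n_pos) + sqrt(N - n_pos))
  list(p_positive = p_pos, p_negative = 1 - p_pos)
}

#' Class-rebalanced bootstrap of a training set
#'
#' Draws `size` samples with replacement: each draw first picks the positive
#' or negative class of function `fn` with the square-root sampling
#' probabilities, then a uniform member of that class. Full label vectors are
#' carried along. Deterministic given the seed.
#'
#' @param data Encoded data set (`X`, `mask`, `Y`, optionally cached `Z`).
#' @param fn Function to rebalance for: a column index or name of `data$Y`.
#' @param size Number of draws (default: the original training-set size `N`).
#' @param seed RNG seed.
#' @return The resampled data set (same structure, `size` samples), with the
#'   drawn row indices in attribute `"indices"`.
#' @export
bootstrap_balanced <- function(data, fn, size = NULL, seed = 1) {
  Y <- data$Y
  c_idx <- if (is.character(fn)) match(fn, colnames(Y)) else fn
  if (is.na(c_idx) || c_idx < 1 || c_idx > ncol(Y)) stop("unknown function: ", fn)
  y <- Y[, c_idx]
  N <- length(y)
  if (is.null(size)) size <- N
  pos <- which(y == 1)
  neg <- which(y == 0)
  fname <- if (!is.null(colnames(Y))) colnames(Y)[c_idx] else as.character(c_idx)
  if (length(pos) == 0)
    stop("function '", fname, "' has no positive samples to resample")
  if (length(neg) == 0)
    stop("function '", fname, "' has no negative samples to resample")
  p <- sampling_probability(length(pos), N)
  idx <- with_seed(seed, {
    take_pos <- runif(size) < p$p_positive
    out <- integer(size)
    out[take_pos] <- pos[sample.int(length(pos), sum(take_pos), replace = TRUE)]
    out[!take_pos] <- neg[sample.int(length(neg), sum(!take_pos), replace = TRUE)]
    out
  })
  res <- subset_data(data, idx)
  attr(res, "indices") <- idx
  res
}

# Subset an encoded data set by (possibly repeated) row indices.
subset_data <- function(data, idx) {
  out <- list()
  if (!is.null(data$X)) out$X <- data$X[, , idx, drop = FALSE]
  if (!is.null(data$mask)) out$mask <- data$mask[, idx, drop = FALSE]
  out$Y <- data$Y[idx, , drop = FALSE]
  if (!is.null(data$Z)) out$Z <- data$Z[, , idx, drop = FALSE]
  if (!is.null(data$ids)) out$ids <- data$ids[idx]
  out
}

#' Retrain one function-specific classifier
#'
#' Retrains classifier `fn` as a binary task on the (typically rebalanced)
#' data set, with the embedding modules and every other function's classifier
#' frozen: only `(w_fn, b_fn)` change, so predictions for all other functions
#' are bit-identical before and after.
#'
#' @param model A fully trained `mp_model` (both phases).
#' @param fn Function index or name.
#' @param data Resampled data set from [bootstrap_balanced()] (uses the
#'   cached `Z` if present, otherwise runs the frozen backbone once).
#' @param config A [training_config()]; retraining uses the phase-2 settings
#'   with `mcrt_epochs` / `mcrt_lr_factor` applied.
#' @param seed RNG seed for batch shuffling.
#' @return The model with classifier `fn` retrained.
#' @export
retrain_classifier <- function(model, fn, data, config = training_config(),
                               seed = 1) {
  stopifnot(inherits(model, "mp_model"))
  if (!("phase2" %in% model$trained_phases))
    stop("classifier retraining requires a fully trained model (both phases)")
  C <- model$config$C
  c_idx <- if (is.character(fn)) match(fn, model$vocab) else fn
  if (is.na(c_idx) || c_idx < 1 || c_idx > C) stop("unknown function: ", fn)
  epochs <- if (is.null(config$mcrt_epochs)) epochs_phase(config, 2)
            else config$mcrt_epochs
  if (epochs == 0) return(model)
  d <- model$config$d_model
  Z <- if (!is.null(data$Z)) data$Z
       else eval_on(model$par, model, data, "specific")$Z
  feat <- t(matrix(Z[c_idx, , ], nrow = d))
  lay <- model$layout
  Wi <- tensor_indices(lay, "W_spec")
  bi <- tensor_indices(lay, "b_spec")
  W <- matrix(model$par[Wi], d, C)
  bvec <- model$par[bi]
  res <- train_one_head(W[, c_idx], bvec[c_idx], feat, data$Y[, c_idx],
                        epochs, config$batch_size,
                        config$learning_rate * config$mcrt_lr_factor,
                        config$weight_decay, config$betas, config$eps, seed)
  W[, c_idx] <- res$w
  bvec[c_idx] <- res$b
  model$par[Wi] <- as.numeric(W)
  model$par[bi] <- bvec
  model$trained_phases <- union(model$trained_phases, "mcrt")
  model
}

#' Run multi-label classifier retraining over all functions
#'
#' For every function in turn: draw a square-root-rebalanced bootstrap of the
#' training set, then retrain that function's classifier with everything else
#' frozen. Per-function seeds are derived from the global seed by function
#' index, so the processing order cannot affect any classifier's outcome.
#'
#' @param model A fully trained `mp_model`.
#' @param train Encoded training set.
#' @param config A [training_config()].
#' @param seed Global seed; per-function sub-seeds are derived from it.
#' @param size Bootstrap size per function (default: training-set size).
#' @return The model with all C classifiers retrained.
#' @export
run_mcrt <- function(model, train, config = training_config(), seed = 1,
                     size = NULL) {
  stopifnot(inherits(model, "mp_model"))
  if (!("phase2" %in% model$trained_phases))
    stop("MCRT requires a fully trained model (both phases)")
  check_data(train, model$config$C, "train")
  # the backbone is frozen throughout: compute representations once
  train$Z <- eval_on(model$par, model, train, "specific")$Z
  for (c_idx in seq_len(model$config$C)) {
    rs <- bootstrap_balanced(train, c_idx, size = size,
                             seed = derive_seed(seed, c_idx))
    model <- retrain_classifier(model, c_idx, rs, config,
                                seed = derive_seed(seed, 100000L + c_idx))
  }
  model
}

#' Construct a weak-label (limited-label) data set
#'
#' Simulates incompletely annotated training data: for each function
#' independently, a uniformly random fraction `wl_ratio` of its positive
#' labels in the in-scope splits (training and validation by default) is
#' flipped to negative — `round(wl_ratio * n_pos)` flips, half-up rounding.
#' Negative labels are never touched, the test split is never degraded, and
#' samples whose label vectors become all-zero are retained as all-negative.
#' The original label matrix is kept alongside for auditing.
#'
#' @param dataset An `mp_dataset` benchmark (see [make_benchmark()]).
#' @param wl_ratio Fraction of positive labels to remove, in `[0, 1]`.
#' @param seed Global seed; per-function sub-seeds are derived from it.
#' @param scope Character vector of split names to degrade
#'   (default `c("train", "val")`).
#' @return The dataset with degraded `Y`, original labels in `Y_original`,
#'   and a `weak_label` provenance record (ratio, seed, flipped entries).
#' @export
make_weak_label_dataset <- function(dataset, wl_ratio, seed = 1,
                                    scope = c("train", "val")) {
  if (wl_ratio < 0 || wl_ratio > 1) stop("wl_ratio must be in [0, 1]")
  stopifnot(!is.null(dataset$Y), !is.null(dataset$split))
  Y0 <- dataset$Y
  Y <- Y0
  in_scope <- sort(unlist(dataset$split[scope], use.names = FALSE))
  flips <- list()
  for (c_idx in seq_len(ncol(Y))) {
    pos <- intersect(which(Y0[, c_idx] == 1), in_scope)
    n_flip <- floor(wl_ratio * length(pos) + 0.5)  # half-up rounding
    if (n_flip == 0) next
    sel <- with_seed(derive_seed(seed, c_idx),
                     pos[sample.int(length(pos), n_flip)])
    Y[sel, c_idx] <- 0L
    flips[[length(flips) + 1]] <- data.frame(row = sel, fn = c_idx)
  }
  dataset$Y <- Y
  dataset$Y_original <- Y0
  dataset$weak_label <- list(
    wl_ratio = wl_ratio, seed = seed, scope = scope,
    flipped = if (length(flips)) do.call(rbind, flips)
              else data.frame(row = integer(0), fn = integer(0)))
  dataset
}
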