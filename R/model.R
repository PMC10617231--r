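# Forward pass and classifier heads. The heavy lifting happens in compiled
# code (src/transformer.cpp); this file provides the user-facing surface:
# function representations Z, attention records, per-function probabilities
# and thresholded label calls.

#' Run the network forward
#'
#' Computes the function representation matrix `Z` (one `d_model`-vector per
#' function class) for each sample, and optionally the full attention record:
#' residue-residue weights from every encoder layer, function-function
#' (decoder self-attention) and function-residue (decoder cross-attention)
#' weights from every decoder layer, one `n_q x n_k x h` array per layer.
#'
#' @param model An `mp_model`.
#' @param x An `mp_encoded` sample from [encode_sample()], or a batch list
#'   with `X` (L x 40 x B array) and `mask` (L x B) from [encode_peptides()].
#' @param Xt Optional C x C function-token input matrix (defaults to the
#'   identity pattern; rows may be permuted to reorder the label tokens).
#' @param attention If `TRUE`, also return attention records.
#' @return A list with `Z` (C x d_model x B array) and, if requested,
#'   `attention` (a list of per-sample records with elements
#'   `residue_residue`, `function_function`, `function_residue`).
#' @export
model_forward <- function(model, x, Xt = NULL, attention = FALSE) {
  stopifnot(inherits(model, "mp_model"))
  cfg <- model$config
  if (inherits(x, "mp_encoded")) {
    X <- array(x$Xs, dim = c(cfg$L, 40, 1))
    mask <- matrix(x$mask * 1, ncol = 1)
  } else {
    X <- x$X
    mask <- x$mask
    if (is.null(dim(mask))) mask <- matrix(mask, ncol = dim(X)[3])
  }
  if (is.null(Xt)) Xt <- diag(cfg$C)
  out <- .cpp_forward(model$par, cfg_list(cfg), X, mask * 1, Xt, attention)
  res <- list(Z = out$Z)
  if (attention) res$attention <- out$attention
  res
}

# Extract classifier heads from a model.
model_heads <- function(model) {
  lay <- model$layout
  d <- model$config$d_model; C <- model$config$C
  list(
    single = list(w = model$par[tensor_indices(lay, "w_single")],
                  b = model$par[tensor_indices(lay, "b_single")]),
    specific = list(W = matrix(model$par[tensor_indices(lay, "W_spec")], d, C),
                    b = model$par[tensor_indices(lay, "b_spec")])
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

as_heads <- function(heads) {
  if (inherits(heads, "mp_model")) model_heads(heads) else heads
}

#' Shared single-classifier probabilities
#'
#' Applies the shared linear classifier to every function's representation
#' row: `p_i = sigmoid(z_i . w_single + b_single)`.
#'
#' @param Z C x d_model function representation matrix (one sample).
#' @param heads An `mp_model`, or a heads list from the model.
#' @return Numeric probability vector of length C.
#' @export
classify_single <- function(Z, heads) {
  h <- as_heads(heads)$single
  as.numeric(sigmoid(Z %*% h$w + h$b))
}

#' Function-specific classifier probabilities
#'
#' Each function uses its own decision boundary on its own representation
#' row: `p_i = sigmoid(w_i . z_i + b_i)`.
#'
#' @inheritParams classify_single
#' @return Numeric probability vector of length C.
#' @export
classify_specific <- function(Z, heads) {
  h <- as_heads(heads)$specific
  u <- colSums(t(Z) * h$W) + h$b
  as.numeric(sigmoid(u))
}

#' Threshold probabilities into a label set
#'
#' A function is called if its probability strictly exceeds the threshold
#' (the default operating point is 0.5; a probability of exactly 0.5 is not
#' called).
#'
#' @param probs Probability vector of length C (optionally named).
#' @param vocab Function names (defaults to `names(probs)`).
#' @param threshold Decision threshold.
#' @return Character vector of called function names.
#' @export
predict_labels <- function(probs, vocab = names(probs), threshold = 0.5) {
  if (is.null(vocab)) stop("no function names available; supply `vocab`")
  vocab[probs > threshold]
}

#' Predict function probabilities for peptides
#'
#' Encodes the peptides, runs the network and applies the classifier heads.
#' After two-phase training the function-specific heads are used; a model
#' that has only completed phase 1 uses the shared single classifier
#' (override with `head`).
#'
#' @param model A trained `mp_model`.
#' @param peps Peptide table from [read_fasta()] or the synthetic generator.
#' @param pssms Optional named list of PSSM matrices keyed by id.
#' @param head `"auto"`, `"single"` or `"specific"`.
#' @param threshold Decision threshold for the calls.
#' @param attention If `TRUE`, also return per-sample attention records.
#' @return A list: `probs` (N x C matrix), `calls` (N x C 0/1 matrix),
#'   `labels` (list of called label sets), optionally `attention`.
#' @export
predict_peptides <- function(model, peps, pssms = NULL,
                             head = c("auto", "single", "specific"),
                             threshold = 0.5, attention = FALSE) {
  head <- match.arg(head)
  if (head == "auto")
    head <- if ("phase2" %in% model$trained_phases) "specific" else "single"
  enc <- encode_peptides(peps, vocab = model$vocab, pssms = pssms,
                         L = model$config$L)
  fw <- model_forward(model, enc, attention = attention)
  probs <- probs_from_Z(fw$Z, model, head)
  dimnames(probs) <- list(peps$id, model$vocab)
  calls <- (probs > threshold) * 1L
  labels <- apply(calls, 1, function(r) model$vocab[r == 1], simplify = FALSE)
  out <- list(probs = probs, calls = calls, labels = labels)
  if (attention) out$attention <- fw$attention
  out
}

# Probabilities for a stack of representations (C x d x B) under either head.
probs_from_Z <- function(Z, model, head = c("specific", "single")) {
  head <- match.arg(head)
  hd <- model_heads(model)
  B <- dim(Z)[3]
  C <- dim(Z)[1]
  probs <- matrix(0, nrow = B, ncol = C)
  if (head == "single") {
    for (b in seq_len(B)) probs[b, ] <- sigmoid(Z[, , b] %*% hd$single$w + hd$single$b)
  } else {
    for (b in seq_len(B)) {
      u <- colSums(t(Z[, , b]) * hd$specific$W) + hd$specific$b
      probs[b, ] <- sigmoid(u)
    }
  }
  probs
}
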