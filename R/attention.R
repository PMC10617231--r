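# Reference attention primitives in plain R. The trained network runs the
# same mathematics in compiled code; these exported building blocks define
# the semantics and are what the test oracles are checked against.

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / base^(2i/d_pe))`,
#' `PE(pos, 2i+1) = cos(pos / base^(2i/d_pe))`, with `pos` running 0..L-1.
#' The base constant defaults to 1000 (the constant this model family uses;
#' the common Transformer default 10000 is available by argument).
#'
#' @param L Number of positions.
#' @param d Encoding width (odd widths are handled by truncating the final
#'   column pair).
#' @param base Base constant (default 1000).
#' @param d_pe Width used in the frequency exponent (defaults to `d`).
#' @return An L x d matrix.
#' @export
positional_encoding <- function(L, d, base = 1000, d_pe = d) {
  pos <- 0:(L - 1)
  pe <- matrix(0, nrow = L, ncol = d)
  for (j in 0:(d - 1)) {
    i <- j %/% 2
    ang <- pos / base^((2 * i) / d_pe)
    pe[, j + 1] <- if (j %% 2 == 0) sin(ang) else cos(ang)
  }
  pe
}

row_softmax <- function(S) {
  E <- exp(sweep(S, 1, apply(S, 1, max), "-"))
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(scale))`, `output = weights V`. The scale
#' defaults to the query width; the network uses its full hidden width
#' `d_model` for every head.
#'
#' @param Q,K,V Query (n_q x d_k), key (n_k x d_k) and value (n_k x d_v)
#'   matrices.
#' @param scale Scalar divisor inside the softmax (as `sqrt(scale)`).
#' @return A list: `output` (n_q x d_v) and `weights` (n_q x n_k, each row a
#'   probability vector).
#' @export
scaled_attention <- function(Q, K, V, scale = ncol(Q)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must have the same width")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  if (!all(is.finite(Q)) || !all(is.finite(K)) || !all(is.finite(V)))
    stop("attention inputs must be finite")
  S <- (Q %*% t(K)) / sqrt(scale)
  W <- row_softmax(matrix(S, nrow = nrow(Q)))
  list(output = W %*% V, weights = W)
}

#' Construct multi-head attention parameters
#'
#' Builds the per-head projection matrices `W_i^Q, W_i^K, W_i^V`
#' (`d_model x d_model/h` each) and the output projection `W^O`
#' (`d_model x d_model`), randomly initialised with a uniform fan-in scheme.
#'
#' @param d_model Hidden width; must be divisible by `h`.
#' @param h Number of heads.
#' @param seed RNG seed for the initialisation.
#' @return A list with elements `Wq`, `Wk`, `Wv` (each a length-`h` list of
#'   `d_model x d_k` matrices) and `Wo` (`d_model x d_model`).
#' @export
mha_params <- function(d_model, h, seed = 1) {
  if (d_model %% h != 0) stop("d_model must be divisible by h")
  dk <- d_model %/% h
  with_seed(seed, {
    mk <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
    list(Wq = replicate(h, mk(d_model, dk), simplify = FALSE),
         Wk = replicate(h, mk(d_model, dk), simplify = FALSE),
         Wv = replicate(h, mk(d_model, dk), simplify = FALSE),
         Wo = mk(d_model, d_model))
  })
}

#' Multi-head attention
#'
#' Computes each head independently via [scaled_attention()] on the projected
#' inputs (all heads share the `sqrt(d_model)` scale), concatenates the head
#' outputs, and applies the output projection.
#'
#' @param X_query n_q x d_model input providing the queries.
#' @param X_keyvalue n_k x d_model input providing keys and values.
#' @param params Parameter list from [mha_params()] (or the same shape).
#' @return A list: `output` (n_q x d_model) and `weights` (length-`h` list of
#'   n_q x n_k attention matrices).
#' @export
multi_head_attention <- function(X_query, X_keyvalue, params) {
  h <- length(params$Wq)
  d_model <- nrow(params$Wq[[1]])
  if (ncol(X_query) != d_model || ncol(X_keyvalue) != d_model)
    stop("inputs must have width d_model = ", d_model)
  outs <- vector("list", h)
  weights <- vector("list", h)
  for (t in seq_len(h)) {
    att <- scaled_attention(X_query %*% params$Wq[[t]],
                            X_keyvalue %*% params$Wk[[t]],
                            X_keyvalue %*% params$Wv[[t]],
                            scale = d_model)
    outs[[t]] <- att$output
    weights[[t]] <- att$weights
  }
  conc <- do.call(cbind, outs)
  list(output = conc %*% params$Wo, weights = weights)
}
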