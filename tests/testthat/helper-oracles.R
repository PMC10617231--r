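# Independent oracles used across the suite. These deliberately re-derive
# every quantity by the most literal possible method (nested loops, explicit
# set arithmetic, exhaustive pair counting) so that they share no code with
# the implementations they check.

# --- attention -------------------------------------------------------------

# scaled dot-product attention via explicit double loops
naive_attention <- function(Q, K, V, scale) {
  n_q <- nrow(Q); n_k <- nrow(K)
  W <- matrix(0, n_q, n_k)
  for (i in seq_len(n_q)) {
    logits <- numeric(n_k)
    for (j in seq_len(n_k)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(scale)
    e <- exp(logits - max(logits))
    W[i, ] <- e / sum(e)
  }
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q))
    for (d in seq_len(ncol(V)))
      out[i, d] <- sum(W[i, ] * V[, d])
  list(output = out, weights = W)
}

# multi-head attention via a per-head loop over naive_attention
naive_mha <- function(Xq, Xkv, params) {
  h <- length(params$Wq)
  d_model <- nrow(params$Wq[[1]])
  pieces <- list()
  for (t in seq_len(h)) {
    att <- naive_attention(Xq %*% params$Wq[[t]], Xkv %*% params$Wk[[t]],
                           Xkv %*% params$Wv[[t]], scale = d_model)
    pieces[[t]] <- att$output
  }
  do.call(cbind, pieces) %*% params$Wo
}

# --- multi-label metrics ---------------------------------------------------

# mean Jaccard via explicit per-sample set arithmetic
oracle_acc_example <- function(Y, Yhat) {
  scores <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    L <- which(Y[i, ] == 1)
    Lh <- which(Yhat[i, ] == 1)
    u <- union(L, Lh)
    scores[i] <- if (length(u) == 0) 1 else length(intersect(L, Lh)) / length(u)
  }
  mean(scores)
}

# macro-F1 via per-function confusion loops
oracle_f1_label <- function(Y, Yhat) {
  f1s <- numeric(ncol(Y))
  for (c in seq_len(ncol(Y))) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(Y))) {
      if (Y[i, c] == 1 && Yhat[i, c] == 1) tp <- tp + 1
      if (Y[i, c] == 0 && Yhat[i, c] == 1) fp <- fp + 1
      if (Y[i, c] == 1 && Yhat[i, c] == 0) fn <- fn + 1
    }
    f1s[c] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(f1s)
}

# AUC by exhaustive concordant/discordant pair counting (ties: half credit)
oracle_auc_pairs <- function(y, scores) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (i in pos)
    for (j in neg)
      total <- total + (if (scores[i] > scores[j]) 1
                        else if (scores[i] == scores[j]) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# MCC straight from a 2x2 table (rows = truth 0/1, cols = prediction 0/1)
oracle_mcc_2x2 <- function(tab) {
  tn <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tp <- tab[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# --- reference forward pass ------------------------------------------------

# A plain-R re-implementation of the network forward pass, built from the
# exported attention primitives, used to cross-check the compiled core on
# tiny configurations.
ref_layer_norm <- function(X, g, b, eps = 1e-5) {
  t(apply(X, 1, function(x) {
    mu <- mean(x); v <- mean((x - mu)^2)
    g * (x - mu) / sqrt(v + eps) + b
  }))
}

ref_forward <- function(model, Xs, mask, Xt = NULL) {
  cfg <- model$config
  lay <- model$layout
  par <- model$par
  d <- cfg$d_model; h <- cfg$h; dk <- d / h
  g <- function(nm) {
    r <- lay[lay$name == nm, ]
    v <- par[seq.int(r$offset, r$offset + r$size - 1)]
    if (r$ncol > 0) matrix(v, r$nrow, r$ncol) else v
  }
  if (is.null(Xt)) Xt <- diag(cfg$C)
  mha_from_pars <- function(Xq, Xkv, prefix, keymask) {
    Q <- sweep(Xq %*% g(paste0(prefix, "_Wq")), 2, g(paste0(prefix, "_bq")), "+")
    K <- sweep(Xkv %*% g(paste0(prefix, "_Wk")), 2, g(paste0(prefix, "_bk")), "+")
    V <- sweep(Xkv %*% g(paste0(prefix, "_Wv")), 2, g(paste0(prefix, "_bv")), "+")
    pieces <- list()
    for (t in seq_len(h)) {
      cols <- ((t - 1) * dk + 1):(t * dk)
      Qh <- Q[, cols, drop = FALSE]
      Kh <- K[, cols, drop = FALSE]
      Vh <- V[, cols, drop = FALSE]
      S <- (Qh %*% t(Kh)) / sqrt(d)
      if (!is.null(keymask)) S[, !keymask] <- -Inf
      W <- t(apply(S, 1, function(s) { e <- exp(s - max(s)); e / sum(e) }))
      pieces[[t]] <- W %*% Vh
    }
    sweep(do.call(cbind, pieces) %*% g(paste0(prefix, "_Wo")), 2,
          g(paste0(prefix, "_bo")), "+")
  }
  ffn <- function(X, prefix) {
    H1 <- sweep(X %*% g(paste0(prefix, "_W1")), 2, g(paste0(prefix, "_b1")), "+")
    H1[H1 < 0] <- 0
    sweep(H1 %*% g(paste0(prefix, "_W2")), 2, g(paste0(prefix, "_b2")), "+")
  }
  km <- if (cfg$mask_padding) as.logical(mask) else NULL
  # input embeddings carry the standard sqrt(d_model) scale before PE
  H <- sweep(Xs %*% g("enc_in_W"), 2, g("enc_in_b"), "+") * sqrt(d) +
    positional_encoding(cfg$L, d, cfg$pe_base, cfg$d_pe)
  for (l in seq_len(cfg$n_enc_layers)) {
    p <- sprintf("enc%d", l)
    A <- mha_from_pars(H, H, paste0(p, "_att"), km)
    H <- ref_layer_norm(H + A, g(paste0(p, "_ln1_g")), g(paste0(p, "_ln1_b")))
    H <- ref_layer_norm(H + ffn(H, paste0(p, "_ff")),
                        g(paste0(p, "_ln2_g")), g(paste0(p, "_ln2_b")))
  }
  D <- sweep(Xt %*% g("dec_in_W"), 2, g("dec_in_b"), "+") * sqrt(d)
  for (l in seq_len(cfg$n_dec_layers)) {
    p <- sprintf("dec%d", l)
    A1 <- mha_from_pars(D, D, paste0(p, "_self"), NULL)
    D <- ref_layer_norm(D + A1, g(paste0(p, "_ln1_g")), g(paste0(p, "_ln1_b")))
    A2 <- mha_from_pars(D, H, paste0(p, "_cross"), km)
    D <- ref_layer_norm(D + A2, g(paste0(p, "_ln2_g")), g(paste0(p, "_ln2_b")))
    D <- ref_layer_norm(D + ffn(D, paste0(p, "_ff")),
                        g(paste0(p, "_ln3_g")), g(paste0(p, "_ln3_b")))
  }
  D
}
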