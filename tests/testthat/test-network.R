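# The Transformer primitives and the compiled forward/backward core.

test_that("positional encoding follows the sinusoidal closed form", {
  pe <- positional_encoding(10, 8, base = 1000)
  # position 0: even columns sin(0) = 0, odd columns cos(0) = 1
  expect_equal(pe[1, c(1, 3, 5, 7)], rep(0, 4))
  expect_equal(pe[1, c(2, 4, 6, 8)], rep(1, 4))
  # first column at position 1 is sin(1), exponent 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  # base constant matters beyond the first pair
  expect_false(isTRUE(all.equal(positional_encoding(10, 8, base = 10000)[, 3],
                                pe[, 3])))
  # compiled core computes the identical matrix
  expect_equal(multipep:::.cpp_positional_encoding(10, 8, 1000, 8), pe,
               tolerance = 1e-14)
})

test_that("scaled attention matches the naive nested-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nq <- sample(1:5, 1); nk <- sample(1:5, 1); dm <- 4
    Q <- matrix(rnorm(nq * dm), nq); K <- matrix(rnorm(nk * dm), nk)
    V <- matrix(rnorm(nk * 3), nk)
    att <- scaled_attention(Q, K, V, scale = dm)
    oracle <- naive_attention(Q, K, V, scale = dm)
    expect_equal(att$output, oracle$output, tolerance = 1e-6)
    expect_equal(att$weights, oracle$weights, tolerance = 1e-6)
    expect_equal(rowSums(att$weights), rep(1, nq), tolerance = 1e-5)
  }
  # single key/value: every weight row is exactly 1, output replicates V
  att1 <- scaled_attention(matrix(rnorm(6), 3), matrix(rnorm(2), 1),
                           matrix(c(5, 7), 1))
  expect_equal(att1$weights, matrix(1, 3, 1))
  expect_equal(att1$output, matrix(c(5, 7, 5, 7, 5, 7), 3, 2, byrow = TRUE))
  # all-equal logits give uniform weights
  att0 <- scaled_attention(matrix(0, 2, 4), matrix(rnorm(12), 3), diag(3))
  expect_equal(att0$weights, matrix(1 / 3, 2, 3))
  expect_error(scaled_attention(matrix(Inf, 1, 2), matrix(0, 1, 2),
                                matrix(0, 1, 1)), "finite")
})

test_that("multi-head attention reduces to scaled attention and matches the oracle", {
  set.seed(7)
  d <- 6
  X <- matrix(rnorm(4 * d), 4)
  # h = 1 with identity projections equals plain scaled attention
  id_params <- list(Wq = list(diag(d)), Wk = list(diag(d)), Wv = list(diag(d)),
                    Wo = diag(d))
  expect_equal(multi_head_attention(X, X, id_params)$output,
               scaled_attention(X, X, X, scale = d)$output, tolerance = 1e-12)
  # h = 2 against the brute-force per-head loop
  params <- mha_params(d, 2, seed = 3)
  Xkv <- matrix(rnorm(3 * d), 3)
  out <- multi_head_attention(X, Xkv, params)
  expect_equal(out$output, naive_mha(X, Xkv, params), tolerance = 1e-6)
  expect_equal(dim(out$output), c(4, d))
  for (W in out$weights) expect_equal(rowSums(W), rep(1, 4), tolerance = 1e-5)
  expect_error(mha_params(7, 2), "divisible")
})

test_that("compiled forward matches the plain-R reference network", {
  cfg <- tiny_config()
  m <- init_model(cfg, function_vocabulary(3), seed = 11)
  batch <- random_batch(cfg, 3, seed = 4)
  fw <- model_forward(m, batch)
  for (b in 1:3) {
    Zref <- ref_forward(m, batch$X[, , b], batch$mask[, b])
    expect_equal(fw$Z[, , b], Zref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("forward pass is deterministic and shape-correct", {
  cfg <- tiny_config()
  m <- init_model(cfg, function_vocabulary(3), seed = 1)
  batch <- random_batch(cfg, 2, seed = 2)
  z1 <- model_forward(m, batch)$Z
  z2 <- model_forward(m, batch)$Z
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(3, 8, 2))
})

test_that("every attention row is a probability vector", {
  cfg <- model_config(d_model = 16, h = 4, n_enc_layers = 2, n_dec_layers = 2,
                      d_ff = 16, L = 10, C = 4)
  m <- init_model(cfg, function_vocabulary(4), seed = 5)
  batch <- random_batch(cfg, 2, seed = 6)
  fw <- model_forward(m, batch, attention = TRUE)
  for (rec in fw$attention) {
    for (layer in rec$residue_residue)
      expect_equal(apply(layer, c(1, 3), sum),
                   matrix(1, dim(layer)[1], dim(layer)[3]), tolerance = 1e-5)
    for (layer in rec$function_function)
      expect_equal(apply(layer, c(1, 3), sum),
                   matrix(1, 4, dim(layer)[3]), tolerance = 1e-5)
    for (layer in rec$function_residue)
      expect_equal(apply(layer, c(1, 3), sum),
                   matrix(1, 4, dim(layer)[3]), tolerance = 1e-5)
  }
})

test_that("padded positions never influence the representations", {
  cfg <- tiny_config()
  m <- init_model(cfg, function_vocabulary(3), seed = 8)
  batch <- random_batch(cfg, 1, seed = 9, min_len = 3)
  n_real <- sum(batch$mask[, 1])
  skip_if(n_real >= cfg$L)  # fixture drew a full-length sequence
  z1 <- model_forward(m, batch)$Z
  batch$X[(n_real + 1):cfg$L, , 1] <- 5  # garbage in the padding rows
  z2 <- model_forward(m, batch)$Z
  expect_identical(z1, z2)
})

test_that("decoder is permutation-equivariant over function tokens, bit-wise", {
  cfg <- model_config(d_model = 32, h = 4, n_enc_layers = 2, n_dec_layers = 2,
                      d_ff = 32, L = 10, C = 5)
  m <- init_model(cfg, function_vocabulary(5), seed = 13)
  batch <- random_batch(cfg, 1, seed = 14)
  Zid <- model_forward(m, batch)$Z[, , 1]
  perm <- c(3, 5, 1, 4, 2)
  P <- diag(5)[perm, ]
  Zperm <- model_forward(m, batch, Xt = P)$Z[, , 1]
  expect_identical(Zperm, Zid[perm, ])
})

test_that("classifier heads compute the documented sigmoids", {
  Z <- matrix(c(1, 0, -1, 2), 2, 2)
  heads <- list(single = list(w = c(0, 0), b = 0),
                specific = list(W = matrix(0, 2, 2), b = c(0, 0)))
  expect_equal(classify_single(Z, heads), c(0.5, 0.5))
  # identical representation rows give identical probabilities
  Zsame <- rbind(c(1, 2), c(1, 2))
  hs <- list(single = list(w = c(0.3, -0.7), b = 0.1))
  expect_equal(classify_single(Zsame, hs)[1], classify_single(Zsame, hs)[2])
  # hand-computed scalar sigmoid oracle
  h2 <- list(single = list(w = c(1, -1), b = 0.5))
  expect_equal(classify_single(Z, h2),
               1 / (1 + exp(-(c(1 * 1 - 1 * (-1), 1 * 0 - 1 * 2) + 0.5))))
  # specific heads reduce to the single head when all parameters coincide
  h3 <- list(single = list(w = c(0.4, 0.2), b = -0.3),
             specific = list(W = cbind(c(0.4, 0.2), c(0.4, 0.2)), b = c(-0.3, -0.3)))
  expect_equal(classify_specific(Z, h3), classify_single(Z, h3))
  # perturbing one function's parameters changes only that probability
  h4 <- h3
  h4$specific$W[, 2] <- c(9, 9)
  p3 <- classify_specific(Z, h3); p4 <- classify_specific(Z, h4)
  expect_equal(p3[1], p4[1])
  expect_false(p3[2] == p4[2])
  # hand oracle for the specific head (z_1 is the first ROW of Z: (1, -1))
  expect_equal(classify_specific(Z, h3)[1],
               1 / (1 + exp(-(0.4 * 1 + 0.2 * (-1) - 0.3))))
})

test_that("predict_labels applies a strict threshold", {
  vocab <- function_vocabulary(5)
  expect_equal(predict_labels(rep(0.4, 5), vocab), character(0))
  probs <- c(0.9, 0.2, 0.6, 0.1, 0.1)
  expect_equal(predict_labels(probs, vocab), vocab[c(1, 3)])
  expect_equal(predict_labels(rep(0.5, 5), vocab), character(0))  # ties excluded
  expect_equal(predict_labels(probs, vocab, threshold = 0), vocab)
})

test_that("compiled gradients match finite differences", {
  cfg <- tiny_config()
  m <- init_model(cfg, function_vocabulary(3), seed = 21)
  batch <- random_batch(cfg, 2, seed = 22)
  cfgl <- multipep:::cfg_list(cfg)
  for (head in c(0L, 1L)) {
    lmask <- if (head == 0L) rep(1, 3) else c(1, 0, 1)
    lg <- multipep:::.cpp_loss_grad(m$par, cfgl, batch$X, batch$mask, batch$Y,
                                    head, lmask, 0, 1L)
    set.seed(23 + head)
    idx <- sample(length(m$par), 120)
    h <- 1e-5
    num <- vapply(idx, function(k) {
      p1 <- m$par; p1[k] <- p1[k] + h
      p2 <- m$par; p2[k] <- p2[k] - h
      (multipep:::.cpp_loss_grad(p1, cfgl, batch$X, batch$mask, batch$Y,
                                 head, lmask, 0, 1L)$loss -
       multipep:::.cpp_loss_grad(p2, cfgl, batch$X, batch$mask, batch$Y,
                                 head, lmask, 0, 1L)$loss) / (2 * h)
    }, numeric(1))
    ana <- lg$grad[idx]
    denom <- pmax(abs(num) + abs(ana), 1e-6)
    expect_lt(max(abs(num - ana) / denom), 1e-3)
  }
})
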