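# Shared fixtures, generated in code. The heavy trained objects used by the
# acceptance tests are memoised in this environment so independent test
# blocks can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_config <- function(...) {
  model_config(d_model = 8, h = 2, n_enc_layers = 1, n_dec_layers = 1,
               d_ff = 12, L = 6, C = 3, ...)
}

# Random encoded batch of B one-hot peptides with variable lengths.
random_batch <- function(cfg, B, seed = 1, min_len = 3) {
  with_seed <- multipep:::with_seed
  with_seed(seed, {
    X <- array(0, c(cfg$L, 40, B))
    mask <- matrix(0, cfg$L, B)
    for (b in seq_len(B)) {
      n <- sample(min_len:cfg$L, 1)
      for (i in seq_len(n)) X[i, sample(20, 1), b] <- 1
      mask[seq_len(n), b] <- 1
    }
    Y <- matrix(rbinom(B * cfg$C, 1, 0.4), B, cfg$C)
    list(X = X, mask = mask, Y = Y)
  })
}

# Tiny but learnable motif data set: C functions, each with an unambiguous
# 3-mer motif, single labels, length exactly L (no padding ambiguity).
motif_batch <- function(cfg, per_class = 4, seed = 1, insertion = 1) {
  motifs <- c("KWK", "CGC", "RPR", "DMD", "VYV", "NFN", "PWP", "TCT")[seq_len(cfg$C)]
  multipep:::with_seed(seed, {
    n <- per_class * cfg$C
    X <- array(0, c(cfg$L, 40, n))
    mask <- matrix(1, cfg$L, n)
    Y <- matrix(0L, n, cfg$C)
    aa <- multipep:::AA_ALPHABET
    k <- 0
    seqs <- character(n)
    for (c in seq_len(cfg$C)) {
      for (r in seq_len(per_class)) {
        k <- k + 1
        chars <- sample(aa, cfg$L, replace = TRUE)
        if (runif(1) < insertion) {
          s <- sample(cfg$L - 3, 1)
          chars[s:(s + 2)] <- strsplit(motifs[c], "")[[1]]
        }
        seqs[k] <- paste(chars, collapse = "")
        enc <- encode_sample(seqs[k], vocab = function_vocabulary(max(cfg$C, 2)),
                             L = cfg$L)
        X[, , k] <- enc$Xs
        Y[k, c] <- 1L
      }
    }
    list(X = X, mask = mask, Y = Y, sequences = seqs)
  })
}

# A small fully trained (phase 1 + 2) model on separable motif data, shared
# by the retraining and freeze-contract tests.
trained_tiny_model <- function() {
  memo("tiny_trained", {
    cfg <- model_config(d_model = 16, h = 2, n_enc_layers = 1, n_dec_layers = 1,
                        d_ff = 16, L = 12, C = 3)
    batch <- motif_batch(cfg, per_class = 6, seed = 51)
    tc <- training_config(epochs = c(8, 4), batch_size = 6, seeds = 1,
                          warmup_steps = 20)
    m <- init_model(cfg, function_vocabulary(3), seed = 51)
    m <- train_phase1(m, batch, batch, tc, seed = 51)
    m <- train_phase2(m, batch, batch, tc, seed = 51)
    list(model = m, data = batch, tc = tc)
  })
}

# Desk-scale benchmark + encoded splits, shared across acceptance blocks.
acceptance_benchmark <- function() {
  memo("bench", {
    bench <- make_benchmark(synthetic_spec())
    list(bench = bench, splits = encode_splits(bench))
  })
}

# Desk-scale model and training configurations for the capacity /
# robustness experiments (the package's study sizes; see the methods
# vignette). The weak-label protocol uses a shorter phase 1 and the
# frozen-backbone phase 2.
desk_model_config <- function(...) model_config(C = 8, dropout = 0.1, ...)

desk_training_config <- function(seeds = 1:5, epochs = c(35, 10),
                                 freeze_eseq_phase2 = FALSE) {
  training_config(learning_rate = 2e-3, weight_decay = 1e-3, batch_size = 16,
                  epochs = epochs, warmup_steps = 100,
                  betas = c(0.9, 0.98), lr_schedule = "constant",
                  freeze_eseq_phase2 = freeze_eseq_phase2, seeds = seeds)
}

wl_training_config <- function(seeds) {
  desk_training_config(seeds = seeds, epochs = c(10, 8),
                       freeze_eseq_phase2 = TRUE)
}

# One full two-phase training on the default benchmark for a given seed.
train_benchmark_model <- function(splits, vocab, seed) {
  tc <- desk_training_config(seeds = seed)
  m <- init_model(desk_model_config(), vocab, seed = seed)
  m <- train_phase1(m, splits$train, splits$val, tc, seed = seed)
  train_phase2(m, splits$train, splits$val, tc, seed = seed)
}
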