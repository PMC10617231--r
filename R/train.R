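# Two-phase training. Phase 1 trains the sequence-embedding module, the
# label-embedding module and the shared single classifier jointly, so that
# every function's representation lives in one common output space. Phase 2
# freezes the label embeddings (by default the whole backbone) and trains the
# function-specific classifiers from a copy of the phase-1 solution. AdamW
# on a flat parameter vector; freezing is index masking, hence bit-exact.

#' Training configuration
#'
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Minibatch size.
#' @param epochs Epochs per training phase: a single number applies to both
#'   phases, a length-2 vector gives (phase 1, phase 2).
#' @param seeds Integer seeds for multi-seed runs (default 5 seeds; averages
#'   are reported across them).
#' @param betas AdamW momentum coefficients.
#' @param eps AdamW denominator epsilon.
#' @param warmup_steps Linear learning-rate warmup over this many optimiser
#'   steps (the post-layer-norm Transformer is warmup-sensitive; 0 disables).
#' @param lr_schedule `"cosine"` (default) decays the learning rate from its
#'   peak to zero over the phase after warmup; `"constant"` holds it fixed.
#' @param freeze_eseq_phase2 If `TRUE` (default), phase 2 also freezes the
#'   sequence-embedding module, keeping the representation geometry fixed
#'   while each function learns its own decision boundary; set `FALSE` to
#'   leave it trainable.
#' @param mcrt_epochs Epochs for per-classifier retraining (default: the
#'   phase-2 epochs).
#' @param mcrt_lr_factor Learning-rate factor applied during classifier
#'   retraining (default 1).
#' @param grid Named list of hyperparameter vectors for [grid_search()].
#' @return An object of class `mp_training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, weight_decay = 1e-2,
                            batch_size = 32, epochs = 30, seeds = 1:5,
                            betas = c(0.9, 0.999), eps = 1e-8,
                            warmup_steps = 100, lr_schedule = c("cosine", "constant"),
                            freeze_eseq_phase2 = TRUE,
                            mcrt_epochs = NULL, mcrt_lr_factor = 1,
                            grid = list()) {
  stopifnot(all(epochs >= 0), length(epochs) %in% c(1, 2), length(seeds) >= 1,
            batch_size >= 1, learning_rate >= 0, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seeds = as.integer(seeds), betas = betas, eps = eps,
                 warmup_steps = as.integer(warmup_steps),
                 lr_schedule = match.arg(lr_schedule),
                 freeze_eseq_phase2 = isTRUE(freeze_eseq_phase2),
                 mcrt_epochs = mcrt_epochs, mcrt_lr_factor = mcrt_lr_factor,
                 grid = grid),
            class = "mp_training_config")
}

epochs_phase <- function(tc, k) tc$epochs[min(k, length(tc$epochs))]

#' Binary cross-entropy loss
#'
#' Standard (negated log-likelihood) binary cross-entropy with probabilities
#' clipped to `[1e-7, 1 - 1e-7]`, summed over the C functions and averaged
#' over samples when matrices are given. Lower is better.
#'
#' @param y_hat Predicted probabilities (vector of length C, or N x C matrix).
#' @param y Binary ground truth of the same shape.
#' @return A scalar loss.
#' @export
bce_loss <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("y_hat and y must have the same length")
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.matrix(y_hat)) mean(rowSums(ll)) else sum(ll)
}

# ---------------------------------------------------------------- AdamW

adamw_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(par, grad, st, idx, lr, wd, betas, eps) {
  st$t <- st$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  st$m[idx] <- b1 * st$m[idx] + (1 - b1) * grad[idx]
  st$v[idx] <- b2 * st$v[idx] + (1 - b2) * grad[idx]^2
  mhat <- st$m[idx] / (1 - b1^st$t)
  vhat <- st$v[idx] / (1 - b2^st$t)
  par[idx] <- par[idx] - lr * (mhat / (sqrt(vhat) + eps) + wd * par[idx])
  list(par = par, state = st)
}

# ------------------------------------------------------------- data plumbing

check_data <- function(data, C, what = "data") {
  if (is.null(data$X) || is.null(data$Y))
    stop(what, " must be a list with X (L x 40 x B), mask (L x B) and Y (B x C)")
  if (dim(data$X)[3] == 0) stop(what, " is empty")
  if (ncol(data$Y) != C) stop(what, "$Y must have C = ", C, " columns")
  if (dim(data$X)[3] != nrow(data$Y)) stop(what, ": X and Y sample counts differ")
  invisible(data)
}

# Forward the whole set (no dropout) and return probabilities and loss.
eval_on <- function(par, model, data, head) {
  cfg <- model$config
  Z <- .cpp_forward(par, cfg_list(cfg), data$X, data$mask * 1, diag(cfg$C), FALSE)$Z
  m2 <- model; m2$par <- par
  probs <- probs_from_Z(Z, m2, head)
  list(probs = probs, loss = bce_loss(probs, data$Y), Z = Z)
}

# Shared minibatch loop over the compiled loss/gradient, updating only
# `trainable_idx`.
train_backbone <- function(model, train, val, tc, head, trainable_idx,
                           epochs, seed, phase_name) {
  cfg <- model$config
  par <- model$par
  B <- dim(train$X)[3]
  st <- adamw_new(length(par))
  lmask <- rep(1, cfg$C)
  head_mode <- if (head == "single") 0L else 1L
  log <- model$log
  step <- 0L
  steps_per_epoch <- length(seq(1, B, by = tc$batch_size))
  total_steps <- epochs * steps_per_epoch
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), sample.int(B))
    starts <- seq(1, B, by = tc$batch_size)
    tl <- 0
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + tc$batch_size - 1, B)]
      lg <- .cpp_loss_grad(par, cfg_list(cfg),
                           train$X[, , idx, drop = FALSE],
                           train$mask[, idx, drop = FALSE] * 1,
                           train$Y[idx, , drop = FALSE],
                           head_mode, lmask, cfg$dropout,
                           derive_seed(seed, epoch * 131071L + k))
      step <- step + 1L
      lr <- tc$learning_rate
      if (tc$warmup_steps > 0) lr <- lr * min(1, step / tc$warmup_steps)
      if (identical(tc$lr_schedule, "cosine") && total_steps > tc$warmup_steps &&
          step > tc$warmup_steps) {
        frac <- (step - tc$warmup_steps) / (total_steps - tc$warmup_steps)
        lr <- lr * 0.5 * (1 + cos(pi * min(frac, 1)))
      }
      up <- adamw_step(par, lg$grad, st, trainable_idx, lr,
                       tc$weight_decay, tc$betas, tc$eps)
      par <- up$par; st <- up$state
      tl <- tl + lg$loss * length(idx)
    }
    vl <- if (!is.null(val)) eval_on(par, model, val, head)$loss else NA_real_
    log <- rbind(log, data.frame(phase = phase_name, epoch = epoch,
                                 train_loss = tl / B, val_loss = vl))
  }
  model$par <- par
  model$log <- log
  model
}

# Minibatch AdamW on a single specific head c over fixed representations.
# feat: B x d feature matrix (the function's representation rows), y: 0/1.
train_one_head <- function(w, b, feat, y, epochs, batch_size, lr, wd, betas, eps,
                           seed) {
  n <- nrow(feat)
  st <- adamw_new(length(w) + 1)
  th <- c(w, b)
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), sample.int(n))
    starts <- seq(1, n, by = batch_size)
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + batch_size - 1, n)]
      Fb <- feat[idx, , drop = FALSE]
      p <- sigmoid(as.numeric(Fb %*% th[-length(th)]) + th[length(th)])
      g <- (p - y[idx]) / length(idx)
      grad <- c(as.numeric(crossprod(Fb, g)), sum(g))
      up <- adamw_step(th, grad, st, seq_along(th), lr, wd, betas, eps)
      th <- up$par; st <- up$state
    }
  }
  list(w = th[-length(th)], b = th[length(th)])
}

#' Train phase 1: embeddings plus the shared classifier
#'
#' Updates the sequence-embedding module, the label-embedding module and the
#' shared single classifier with AdamW for the configured number of epochs;
#' the function-specific classifiers are untouched. Per-epoch training and
#' validation losses are appended to the model log.
#'
#' @param model A freshly initialised `mp_model`.
#' @param train,val Encoded data sets: lists with `X` (L x 40 x B array),
#'   `mask` (L x B) and `Y` (B x C), e.g. from [encode_splits()].
#' @param config An [training_config()].
#' @param seed Run seed controlling batch shuffling (and dropout).
#' @return The trained model.
#' @export
train_phase1 <- function(model, train, val = NULL, config = training_config(),
                         seed = model$seed) {
  stopifnot(inherits(model, "mp_model"))
  check_data(train, model$config$C, "train")
  gi <- param_group_indices(model$layout)
  trainable <- c(gi$E_seq, gi$E_func, gi$F_single)
  model <- train_backbone(model, train, val, config, "single", trainable,
                          epochs_phase(config, 1), seed, "phase1")
  model$trained_phases <- union(model$trained_phases, "phase1")
  model
}

#' Train phase 2: function-specific classifiers
#'
#' Replaces the shared classifier with C function-specific classifiers, each
#' initialised from the phase-1 solution, and trains them with the
#' label-embedding module frozen (bit-identical before/after). By default the
#' sequence-embedding module is frozen too, in which case the function
#' representations are precomputed once and only the C linear heads are
#' optimised — mathematically identical to running the full network with a
#' frozen backbone. Inference afterwards routes through [classify_specific()].
#'
#' @inheritParams train_phase1
#' @return The trained model (phase 2 complete).
#' @export
train_phase2 <- function(model, train, val = NULL, config = training_config(),
                         seed = model$seed) {
  stopifnot(inherits(model, "mp_model"))
  if (!("phase1" %in% model$trained_phases))
    stop("phase 2 requires a phase-1-trained model")
  check_data(train, model$config$C, "train")
  lay <- model$layout
  d <- model$config$d_model; C <- model$config$C
  # initialise every specific classifier from the shared one
  w1 <- model$par[tensor_indices(lay, "w_single")]
  b1 <- model$par[tensor_indices(lay, "b_single")]
  model$par[tensor_indices(lay, "W_spec")] <- rep(w1, C)
  model$par[tensor_indices(lay, "b_spec")] <- rep(b1, C)
  epochs <- epochs_phase(config, 2)
  if (epochs > 0) {
    if (config$freeze_eseq_phase2) {
      model <- train_heads_cached(model, train, val, config, seq_len(C),
                                  epochs, seed, "phase2")
    } else {
      gi <- param_group_indices(lay)
      trainable <- c(gi$E_seq, gi$F_specific)
      model <- train_backbone(model, train, val, config, "specific", trainable,
                              epochs, seed, "phase2")
    }
  }
  model$trained_phases <- union(model$trained_phases, "phase2")
  model
}

# Frozen-backbone training of the specific heads in `cs` on cached Z.
train_heads_cached <- function(model, train, val, tc, cs, epochs, seed,
                               phase_name, lr = tc$learning_rate) {
  lay <- model$layout
  d <- model$config$d_model; C <- model$config$C
  Ztr <- if (!is.null(train$Z)) train$Z
         else eval_on(model$par, model, train, "specific")$Z
  Wi <- tensor_indices(lay, "W_spec")
  bi <- tensor_indices(lay, "b_spec")
  W <- matrix(model$par[Wi], d, C)
  bvec <- model$par[bi]
  for (c in cs) {
    feat <- t(matrix(Ztr[c, , ], nrow = d))
    res <- train_one_head(W[, c], bvec[c], feat, train$Y[, c], epochs,
                          tc$batch_size, lr, tc$weight_decay, tc$betas,
                          tc$eps, derive_seed(seed, c))
    W[, c] <- res$w
    bvec[c] <- res$b
  }
  model$par[Wi] <- as.numeric(W)
  model$par[bi] <- bvec
  if (!is.null(val) || !is.null(train)) {
    trl <- eval_on(model$par, model, train, "specific")$loss
    vl <- if (!is.null(val)) eval_on(model$par, model, val, "specific")$loss else NA_real_
    model$log <- rbind(model$log,
                       data.frame(phase = phase_name, epoch = epochs,
                                  train_loss = trl, val_loss = vl))
  }
  model
}

#' Grid search over hyperparameters
#'
#' Trains the full two-phase pipeline for every combination in the search
#' space and returns the combination with the minimum final validation loss,
#' together with the complete (configuration, validation loss) table.
#' Space entries whose names match [model_config()] arguments modify the
#' architecture; the rest modify the training configuration.
#'
#' @param space Named list of value vectors, e.g.
#'   `list(learning_rate = c(1e-3, 1e-4), d_model = c(32, 64))`.
#' @param train,val Encoded data sets.
#' @param model_cfg Base [model_config()].
#' @param config Base [training_config()] (its `epochs` can be reduced for
#'   the search).
#' @param vocab Function vocabulary.
#' @param seed Seed used for every candidate (same initialisation draw).
#' @return A list: `best_model_config`, `best_training_config`, `best_val_loss`,
#'   and `table` (one row per configuration with its validation loss).
#' @export
grid_search <- function(space, train, val, model_cfg = model_config(),
                        config = training_config(), vocab = NULL, seed = 1) {
  if (length(space) == 0 || any(lengths(space) == 0))
    stop("grid-search space is empty")
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  mc_names <- names(formals(model_config))
  if (is.null(vocab)) vocab <- function_vocabulary(model_cfg$C)
  losses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mc <- model_cfg; tc <- config
    for (nm in names(grid)) {
      if (nm %in% mc_names) mc[[nm]] <- grid[[nm]][i] else tc[[nm]] <- grid[[nm]][i]
    }
    mc <- do.call(model_config, mc[mc_names[mc_names %in% names(mc)]])
    m <- init_model(mc, vocab, seed = seed)
    m <- train_phase1(m, train, val, tc, seed = seed)
    m <- train_phase2(m, train, val, tc, seed = seed)
    losses[i] <- utils::tail(m$log$val_loss[!is.na(m$log$val_loss)], 1)
  }
  grid$val_loss <- losses
  best <- which.min(losses)
  mc <- model_cfg; tc <- config
  for (nm in names(space)) {
    if (nm %in% mc_names) mc[[nm]] <- grid[[nm]][best] else tc[[nm]] <- grid[[nm]][best]
  }
  mc <- do.call(model_config, mc[mc_names[mc_names %in% names(mc)]])
  list(best_model_config = mc, best_training_config = tc,
       best_val_loss = losses[best], table = grid)
}

#' Train across several seeds and average the evaluation
#'
#' Runs the full two-phase pipeline once per seed, evaluates each trained
#' model on the test split, and reports per-seed metrics together with their
#' arithmetic mean.
#'
#' @param splits List with `train`, `val`, `test` encoded data sets
#'   (see [encode_splits()]).
#' @param model_cfg A [model_config()].
#' @param config A [training_config()]; its `seeds` field drives the runs.
#' @param vocab Function vocabulary.
#' @return A list: `models` (one per seed), `per_seed` (data.frame with
#'   `seed`, `acc_example`, `f1_label`), `mean` (named list of averaged
#'   metrics), `reports` (full per-seed metric reports).
#' @export
train_multiseed <- function(splits, model_cfg = model_config(),
                            config = training_config(), vocab = NULL) {
  if (is.null(vocab)) vocab <- function_vocabulary(model_cfg$C)
  models <- list()
  reports <- list()
  rows <- list()
  for (s in config$seeds) {
    m <- init_model(model_cfg, vocab, seed = s)
    m <- train_phase1(m, splits$train, splits$val, config, seed = s)
    m <- train_phase2(m, splits$train, splits$val, config, seed = s)
    ev <- eval_on(m$par, m, splits$test, "specific")
    rep <- metrics_report(splits$test$Y, ev$probs)
    models[[as.character(s)]] <- m
    reports[[as.character(s)]] <- rep
    rows[[length(rows) + 1]] <- data.frame(seed = s,
                                           acc_example = rep$acc_example,
                                           f1_label = rep$f1_label)
  }
  per_seed <- do.call(rbind, rows)
  list(models = models, per_seed = per_seed,
       mean = list(acc_example = mean(per_seed$acc_example),
                   f1_label = mean(per_seed$f1_label)),
       reports = reports)
}
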