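# Model configuration, the canonical flat-parameter layout, and seeded
# initialisation. The layout here must mirror the unpacking order in
# src/transformer.cpp exactly; init_model() cross-checks the total length
# against the compiled side.

#' Model configuration
#'
#' Architecture hyperparameters of the label-embedding Transformer. Defaults
#' are the desk-scale configuration used throughout the package's tests and
#' examples (2 encoder + 2 decoder layers, `d_model = 64`, 4 heads); larger
#' values are plain configuration inputs.
#'
#' @param d_model Hidden width; must be divisible by `h`.
#' @param h Number of attention heads.
#' @param n_enc_layers,n_dec_layers Encoder/decoder layer counts.
#' @param d_ff Feed-forward inner width (default `2 * d_model`).
#' @param dropout Dropout rate in `[0, 1)` applied to sublayer outputs during
#'   training (0 disables it and makes training fully deterministic given the
#'   seed).
#' @param L Fixed sequence length (default 50; must be even).
#' @param C Number of function classes.
#' @param pe_base Positional-encoding base constant (default 1000).
#' @param d_pe Positional-encoding width parameter (defaults to `d_model`).
#' @param mask_padding If `TRUE` (default), padded positions are excluded
#'   from encoder self-attention and decoder cross-attention keys, so padding
#'   can never influence the function representations.
#' @return An object of class `mp_model_config`.
#' @export
model_config <- function(d_model = 64, h = 4, n_enc_layers = 2, n_dec_layers = 2,
                         d_ff = 2 * d_model, dropout = 0, L = 50, C = 15,
                         pe_base = 1000, d_pe = d_model, mask_padding = TRUE) {
  stopifnot(d_model >= 1, h >= 1, n_enc_layers >= 1, n_dec_layers >= 1,
            d_ff >= 1, L >= 2, C >= 2)
  if (d_model %% h != 0) stop("d_model must be divisible by h")
  if (L %% 2 != 0) stop("L must be even (pad/truncate takes L/2 from each terminus)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(d_model = as.integer(d_model), h = as.integer(h),
                 n_enc_layers = as.integer(n_enc_layers),
                 n_dec_layers = as.integer(n_dec_layers),
                 d_ff = as.integer(d_ff), dropout = dropout,
                 L = as.integer(L), C = as.integer(C),
                 pe_base = pe_base, d_pe = as.integer(d_pe),
                 mask_padding = isTRUE(mask_padding)),
            class = "mp_model_config")
}

#' @export
print.mp_model_config <- function(x, ...) {
  cat(sprintf(
    "Label-embedding Transformer config: d_model=%d h=%d enc=%d dec=%d d_ff=%d L=%d C=%d\n",
    x$d_model, x$h, x$n_enc_layers, x$n_dec_layers, x$d_ff, x$L, x$C))
  cat(sprintf("  dropout=%g pe_base=%g mask_padding=%s\n",
              x$dropout, x$pe_base, x$mask_padding))
  invisible(x)
}

#' Flat parameter layout
#'
#' Describes the canonical packing of all trainable tensors into one numeric
#' vector: tensor name, start offset, length, shape, and parameter group.
#' The four groups — `E_seq` (sequence-embedding module), `E_func`
#' (label-embedding module), `F_single` (shared classifier) and `F_specific`
#' (function-specific classifiers) — partition the vector; training phases
#' and retraining freeze or update whole groups by index.
#'
#' @param config An `mp_model_config`.
#' @return A data.frame with columns `name`, `offset` (1-based start),
#'   `size`, `nrow`, `ncol`, `group`, `kind`.
#' @export
param_layout <- function(config) {
  d <- config$d_model; f <- config$d_ff; C <- config$C
  rows <- list()
  off <- 1L
  add <- function(name, nrow, ncol, group, kind) {
    size <- nrow * max(ncol, 1L)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, offset = off, size = size,
      nrow = nrow, ncol = ncol, group = group, kind = kind,
      stringsAsFactors = FALSE)
    off <<- off + as.integer(size)
  }
  add_attn <- function(prefix, group) {
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      add(paste0(prefix, "_", nm), d, d, group, "weight")
      add(paste0(prefix, "_b", substr(nm, 2, 2)), d, 0L, group, "bias")
    }
  }
  add_ln <- function(prefix, group) {
    add(paste0(prefix, "_g"), d, 0L, group, "ln_gain")
    add(paste0(prefix, "_b"), d, 0L, group, "bias")
  }
  add_ff <- function(prefix, group) {
    add(paste0(prefix, "_W1"), d, f, group, "weight")
    add(paste0(prefix, "_b1"), f, 0L, group, "bias")
    add(paste0(prefix, "_W2"), f, d, group, "weight")
    add(paste0(prefix, "_b2"), d, 0L, group, "bias")
  }
  add("enc_in_W", 40L, d, "E_seq", "weight")
  add("enc_in_b", d, 0L, "E_seq", "bias")
  for (l in seq_len(config$n_enc_layers)) {
    p <- sprintf("enc%d", l)
    add_attn(paste0(p, "_att"), "E_seq")
    add_ln(paste0(p, "_ln1"), "E_seq")
    add_ff(paste0(p, "_ff"), "E_seq")
    add_ln(paste0(p, "_ln2"), "E_seq")
  }
  add("dec_in_W", C, d, "E_func", "weight")
  add("dec_in_b", d, 0L, "E_func", "bias")
  for (l in seq_len(config$n_dec_layers)) {
    p <- sprintf("dec%d", l)
    add_attn(paste0(p, "_self"), "E_func")
    add_ln(paste0(p, "_ln1"), "E_func")
    add_attn(paste0(p, "_cross"), "E_func")
    add_ln(paste0(p, "_ln2"), "E_func")
    add_ff(paste0(p, "_ff"), "E_func")
    add_ln(paste0(p, "_ln3"), "E_func")
  }
  add("w_single", d, 0L, "F_single", "weight")
  add("b_single", 1L, 0L, "F_single", "bias")
  add("W_spec", d, C, "F_specific", "weight")
  add("b_spec", C, 0L, "F_specific", "bias")
  do.call(rbind, rows)
}

# Named list of index vectors, one per parameter group.
param_group_indices <- function(layout) {
  idx <- lapply(split(layout, layout$group), function(g) {
    unlist(mapply(function(o, s) seq.int(o, o + s - 1), g$offset, g$size,
                  SIMPLIFY = FALSE), use.names = FALSE)
  })
  idx[c("E_seq", "E_func", "F_single", "F_specific")]
}

# Index range of one named tensor.
tensor_indices <- function(layout, name) {
  r <- layout[layout$name == name, ]
  if (nrow(r) != 1) stop("unknown tensor: ", name)
  seq.int(r$offset, r$offset + r$size - 1)
}

# Configuration list handed to the compiled core.
cfg_list <- function(config) {
  config[c("d_model", "h", "n_enc_layers", "n_dec_layers", "d_ff", "L", "C",
           "mask_padding", "pe_base", "d_pe")]
}

#' Initialise a model
#'
#' Creates a model with seeded uniform fan-in weight initialisation
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`), zero biases, and unit layer-norm
#' gains. The output projections of the residual branches (attention `Wo`
#' and feed-forward `W2`) are additionally scaled down by `residual_scale`,
#' which keeps each sublayer close to the identity at initialisation — a
#' standard stabilisation for post-layer-norm Transformers that lets them
#' train without long warmup. The caller's RNG state is left untouched.
#'
#' @param config An [model_config()].
#' @param vocab Function vocabulary; its length must equal `config$C`.
#' @param seed Integer seed controlling the initialisation.
#' @param residual_scale Multiplier on the residual-branch output
#'   projections at initialisation (default 0.25; 1 recovers the plain
#'   fan-in scheme).
#' @return An object of class `mp_model`: list with `config`, `vocab`, `par`
#'   (flat numeric parameter vector), `layout`, `trained_phases`, `log`.
#' @export
init_model <- function(config, vocab = function_vocabulary(config$C), seed = 1,
                       residual_scale = 0.25) {
  stopifnot(inherits(config, "mp_model_config"))
  if (length(vocab) != config$C)
    stop("vocabulary length (", length(vocab), ") must equal config$C (", config$C, ")")
  layout <- param_layout(config)
  n <- sum(layout$size)
  n_cpp <- .cpp_param_count(cfg_list(config))
  if (n != n_cpp)
    stop("internal error: R layout (", n, ") and compiled layout (", n_cpp,
         ") disagree")
  par <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(nrow(layout))) {
      r <- layout[i, ]
      idx <- seq.int(r$offset, r$offset + r$size - 1)
      par[idx] <- switch(r$kind,
        weight = {
          fan_in <- r$nrow
          runif(r$size, -1, 1) / sqrt(fan_in)
        },
        bias = 0,
        ln_gain = 1)
      if (grepl("(_Wo|_W2)$", r$name)) par[idx] <- par[idx] * residual_scale
    }
  })
  structure(list(config = config, vocab = vocab, par = par, layout = layout,
                 seed = as.integer(seed),
                 trained_phases = character(0),
                 log = data.frame()),
            class = "mp_model")
}

#' @export
print.mp_model <- function(x, ...) {
  cat("Label-embedding Transformer model\n")
  print(x$config)
  cat(sprintf("  vocabulary: %s\n", paste(x$vocab, collapse = ", ")))
  cat(sprintf("  parameters: %d  trained: %s\n", length(x$par),
              if (length(x$trained_phases)) paste(x$trained_phases, collapse = " + ")
              else "none"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the configuration, the
#' function vocabulary, the flat parameter vector and the training log.
#'
#' @param model An `mp_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored `mp_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mp_model")) stop("not a model checkpoint: ", path)
  model
}
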