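# Synthetic multi-label peptide benchmarks with the statistical structure the
# method assumes: a long-tail per-function sample distribution, samples
# carrying 1-4 correlated labels (drawn from weighted label templates), and a
# distinct sequence motif per function so the labels are learnable from
# sequence alone. Everything is deterministic given (spec, seed).

# Distinct default 4-mer motifs, assigned to the canonical vocabulary order.
DEFAULT_MOTIFS <- c(AMP = "KWKR", TXP = "GCHC", ABP = "RLWP", AIP = "DEMD",
                    AVP = "VHYV", ACP = "NQFN", AFP = "PYWP", DDV = "TSCT",
                    CPP = "IMHI", CCC = "EAWE", APP = "QFRQ", AAP = "LDCL",
                    AHTP = "WGSW", PBP = "HKMH", QSP = "CVYC")

#' Synthetic benchmark specification
#'
#' Defines the generative model of the synthetic benchmark: per-function base
#' weights follow a power-law tail (`rank^-tail_exponent`), label sets are
#' drawn from weighted templates (singletons plus overlapping pairs and
#' triples of adjacent functions, which induces positive label correlations),
#' and each function has a distinct k-mer motif inserted into its positive
#' sequences with probability `insertion_prob`.
#'
#' @param C Number of functions (default 8; uses the first C names of the
#'   canonical vocabulary).
#' @param n_samples Number of peptides (default 2000).
#' @param length_range Sequence length range (default 15-50).
#' @param tail_exponent Power-law exponent of the per-function weights
#'   (0 = uniform; default 1.5 gives a pronounced long tail).
#' @param insertion_prob Probability that a label's motif is actually
#'   inserted into a positive sequence (label-conditional signal strength;
#'   default 0.9, must exceed 0.5 for a learnable fixture).
#' @param motifs Named character vector function -> motif (defaults to the
#'   built-in distinct 4-mers).
#' @param templates Optional list of label-set templates with a `weight`
#'   attribute each; `NULL` builds the default template set.
#' @param background Background residue distribution: `"uniform"` or a named
#'   probability vector over the 20 amino acids.
#' @param seed Generator seed.
#' @return An object of class `mp_synth_spec`.
#' @export
synthetic_spec <- function(C = 8, n_samples = 2000, length_range = c(15, 50),
                           tail_exponent = 1.5, insertion_prob = 0.9,
                           motifs = NULL, templates = NULL,
                           background = "uniform", seed = 42) {
  vocab <- function_vocabulary(C)
  if (is.null(motifs)) motifs <- DEFAULT_MOTIFS[vocab]
  if (is.null(names(motifs))) names(motifs) <- vocab
  if (anyDuplicated(motifs)) stop("motifs must be distinct across functions")
  if (insertion_prob <= 0.5 || insertion_prob > 1)
    stop("insertion_prob must be in (0.5, 1] for a learnable fixture")
  if (is.null(templates)) templates <- default_templates(vocab, tail_exponent)
  w <- vapply(templates, function(t) attr(t, "weight"), numeric(1))
  if (any(w <= 0)) stop("template weights must be positive")
  structure(list(C = as.integer(C), vocab = vocab,
                 n_samples = as.integer(n_samples),
                 length_range = as.integer(length_range),
                 tail_exponent = tail_exponent,
                 insertion_prob = insertion_prob,
                 motifs = motifs, templates = templates,
                 background = background, seed = as.integer(seed)),
            class = "mp_synth_spec")
}

# Singleton, adjacent-pair and adjacent-triple label templates whose weights
# decay with function rank, producing a long-tail count distribution with
# positive co-occurrence correlations between neighbouring functions.
default_templates <- function(vocab, tail_exponent) {
  C <- length(vocab)
  base <- (seq_len(C))^(-tail_exponent)
  tmpl <- list()
  add <- function(fns, w) {
    t <- fns; attr(t, "weight") <- w
    tmpl[[length(tmpl) + 1]] <<- t
  }
  for (c in seq_len(C)) add(vocab[c], base[c])
  for (c in seq_len(C - 1)) add(vocab[c:(c + 1)], 0.35 * sqrt(base[c] * base[c + 1]))
  for (c in seq_len(max(C - 2, 0))) add(vocab[c:(c + 2)], 0.12 * (base[c] * base[c + 1] * base[c + 2])^(1 / 3))
  tmpl
}

#' Draw label sets from the template distribution
#'
#' @param spec An [synthetic_spec()].
#' @param n Number of samples (default `spec$n_samples`).
#' @param seed Seed (default `spec$seed`).
#' @return A list of character label sets.
#' @export
sample_label_sets <- function(spec, n = spec$n_samples, seed = spec$seed) {
  w <- vapply(spec$templates, function(t) attr(t, "weight"), numeric(1))
  w <- w / sum(w)
  idx <- with_seed(seed, sample.int(length(spec$templates), n, replace = TRUE,
                                    prob = w))
  lapply(idx, function(i) as.character(spec$templates[[i]]))
}

# Background residue sampler.
draw_background <- function(len, background) {
  if (identical(background, "uniform")) {
    sample(AA_ALPHABET, len, replace = TRUE)
  } else {
    sample(names(background), len, replace = TRUE, prob = background)
  }
}

#' Generate peptide sequences for given label sets
#'
#' Each peptide is drawn from the background residue distribution; for each
#' of its labels, the function's motif is written at a uniformly chosen
#' position that does not overlap previously inserted motifs, with
#' probability `insertion_prob`. If a sequence is too short to host all its
#' motifs it is regenerated at the maximum length (logged via a message).
#'
#' @param label_sets List of character label sets (see [sample_label_sets()]).
#' @param spec An [synthetic_spec()].
#' @param seed Seed (default `spec$seed + 1` so labels and sequences use
#'   independent streams).
#' @return A list: `peptides` (data.frame `id`, `sequence`, `labels`) and
#'   `Y` (N x C binary matrix).
#' @export
generate_peptides <- function(label_sets, spec, seed = spec$seed + 1) {
  n <- length(label_sets)
  vocab <- spec$vocab
  if (!all(unlist(label_sets) %in% vocab))
    stop("label sets contain functions missing from the motif table")
  k <- unique(nchar(spec$motifs))
  if (length(k) > 1) k <- max(k)
  seqs <- character(n)
  Y <- matrix(0L, nrow = n, ncol = spec$C, dimnames = list(NULL, vocab))
  resampled <- 0
  with_seed(seed, {
    for (i in seq_len(n)) {
      labs <- label_sets[[i]]
      Y[i, labs] <- 1L
      len <- sample(spec$length_range[1]:spec$length_range[2], 1)
      insert <- labs[runif(length(labs)) < spec$insertion_prob]
      need <- length(insert) * k
      if (need > len) {
        len <- spec$length_range[2]
        resampled <- resampled + 1
        if (need > len) insert <- insert[seq_len(len %/% k)]
      }
      chars <- draw_background(len, spec$background)
      occupied <- logical(len)
      for (fn in insert) {
        motif <- strsplit(spec$motifs[[fn]], "")[[1]]
        free <- which(vapply(seq_len(len - k + 1),
                             function(s) !any(occupied[s:(s + k - 1)]),
                             logical(1)))
        if (length(free) == 0) next
        s <- free[sample.int(length(free), 1)]
        chars[s:(s + k - 1)] <- motif
        occupied[s:(s + k - 1)] <- TRUE
      }
      seqs[i] <- paste(chars, collapse = "")
    }
  })
  if (resampled > 0)
    message(resampled, " sequence(s) regenerated at maximum length to host all motifs")
  peps <- peptides(sprintf("syn%05d", seq_len(n)), seqs, labels = label_sets)
  rownames(Y) <- peps$id
  list(peptides = peps, Y = Y)
}

#' Split samples into train / validation / test
#'
#' Seeded random split with the given ratios (default 8:1:1). When a label
#' matrix is supplied the split is best-effort stratified: any function with
#' positives overall but none in the training split gets one of its positive
#' samples swapped into training.
#'
#' @param n Number of samples (or a label matrix `Y`, in which case
#'   stratification is applied).
#' @param ratios Numeric length-3 vector, normalised to sum to 1.
#' @param seed Seed.
#' @return A list of index vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(n, ratios = c(8, 1, 1), seed = 1) {
  Y <- NULL
  if (is.matrix(n)) { Y <- n; n <- nrow(Y) }
  if (n < 3) stop("need at least 3 samples to split")
  if (length(ratios) != 3 || any(ratios <= 0)) stop("ratios must be 3 positive numbers")
  ratios <- ratios / sum(ratios)
  with_seed(seed, {
    ord <- sample.int(n)
    n_train <- round(ratios[1] * n)
    n_val <- round(ratios[2] * n)
    split <- list(train = sort(ord[seq_len(n_train)]),
                  val = sort(ord[n_train + seq_len(n_val)]),
                  test = sort(ord[(n_train + n_val + 1):n]))
    if (!is.null(Y)) {
      for (c in seq_len(ncol(Y))) {
        pos <- which(Y[, c] == 1)
        if (length(pos) == 0 || any(pos %in% split$train)) next
        take <- pos[sample.int(length(pos), 1)]
        from <- if (take %in% split$val) "val" else "test"
        give <- split$train[sample.int(length(split$train), 1)]
        split$train <- sort(c(setdiff(split$train, integer(0)), take))
        split[[from]] <- sort(c(setdiff(split[[from]], take), give))
        split$train <- sort(setdiff(split$train, give))
      }
    }
    split
  })
}

#' Generate a complete synthetic benchmark
#'
#' Label sets, sequences and the 8:1:1 split in one call.
#'
#' @param spec An [synthetic_spec()].
#' @return An object of class `mp_dataset`: list with `peptides`, `Y`,
#'   `vocab`, `split` and `spec`.
#' @export
make_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "mp_synth_spec"))
  sets <- sample_label_sets(spec)
  gen <- generate_peptides(sets, spec)
  split <- split_dataset(gen$Y, seed = spec$seed + 2)
  structure(list(peptides = gen$peptides, Y = gen$Y, vocab = spec$vocab,
                 split = split, spec = spec),
            class = "mp_dataset")
}

#' Encode a benchmark's splits for training
#'
#' @param dataset An `mp_dataset`.
#' @param L Model length.
#' @return A list of encoded sets `train`, `val`, `test`, each with `X`,
#'   `mask`, `Y`, `ids`.
#' @export
encode_splits <- function(dataset, L = 50) {
  enc <- encode_peptides(dataset$peptides, vocab = dataset$vocab, L = L)
  lapply(dataset$split, function(idx) {
    list(X = enc$X[, , idx, drop = FALSE],
         mask = enc$mask[, idx, drop = FALSE],
         Y = dataset$Y[idx, , drop = FALSE],
         ids = enc$ids[idx])
  })
}

#' Write a benchmark to disk
#'
#' Emits FASTA sequences, the binary label table (TSV), the split membership
#' (TSV) and a JSON sidecar with the full generator provenance.
#'
#' @param dataset An `mp_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$peptides, file.path(dir, "peptides.fasta"))
  write_label_table(dataset$peptides$id, dataset$Y, file.path(dir, "labels.tsv"))
  split_df <- data.frame(
    id = dataset$peptides$id,
    split = NA_character_)
  for (nm in names(dataset$split)) split_df$split[dataset$split[[nm]]] <- nm
  utils::write.table(split_df, file.path(dir, "splits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  spec <- dataset$spec
  sidecar <- list(C = spec$C, vocab = spec$vocab, n_samples = spec$n_samples,
                  length_range = spec$length_range,
                  tail_exponent = spec$tail_exponent,
                  insertion_prob = spec$insertion_prob,
                  motifs = as.list(spec$motifs),
                  background = spec$background, seed = spec$seed,
                  templates = lapply(spec$templates, function(t)
                    list(labels = as.character(t), weight = attr(t, "weight"))))
  jsonlite::write_json(sidecar, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
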