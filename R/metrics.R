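# Multi-label evaluation: example-based accuracy (mean per-sample Jaccard),
# label-based macro-F1, one-vs-all binary metrics (AUC, MCC, F1, RkCC),
# shot-group stratified reports, Pearson correlation matrices and attention
# summaries.

check_same_shape <- function(Y, Yhat) {
  if (!is.matrix(Y) || !is.matrix(Yhat) ||
      !identical(unname(dim(Y)), unname(dim(Yhat))))
    stop("label matrices must have the same shape")
}

#' Example-based accuracy (mean Jaccard index)
#'
#' Mean over samples of `|L ∩ L̂| / |L ∪ L̂|` between the true and predicted
#' label sets. A sample where both sets are empty scores 1 (perfectly
#' predicted absence); the number of such samples is attached as attribute
#' `"both_empty"` since data sets with at least one label per sample never
#' hit this convention.
#'
#' @param Y,Yhat N x C binary matrices (truth, predictions).
#' @return Scalar in `[0, 1]`.
#' @export
acc_example <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  inter <- rowSums(Y * Yhat)
  uni <- rowSums((Y + Yhat) > 0)
  scores <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  structure(mean(scores), both_empty = sum(uni == 0))
}

#' Label-based macro F1
#'
#' Unweighted mean over functions of the per-function binary F1 score.
#' A function with no positives and no positive predictions contributes 0
#' (the zero-division convention; such columns are counted in attribute
#' `"degenerate"`).
#'
#' @param Y,Yhat N x C binary matrices.
#' @return Scalar in `[0, 1]`.
#' @export
f1_label <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  f1s <- vapply(seq_len(ncol(Y)), function(c) {
    tp <- sum(Y[, c] == 1 & Yhat[, c] == 1)
    fp <- sum(Y[, c] == 0 & Yhat[, c] == 1)
    fn <- sum(Y[, c] == 1 & Yhat[, c] == 0)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  structure(mean(f1s), per_function = f1s,
            degenerate = sum(colSums(Y) == 0 & colSums(Yhat) == 0))
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' One-vs-all binary metrics for a single function
#'
#' AUC by the Mann–Whitney rank method (ties receive half credit); MCC, F1,
#' precision and recall from the confusion counts at the given threshold.
#' AUC is `NA` when only one class is present.
#'
#' @param y Binary truth vector.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold (default 0.5, strict `>`).
#' @return Named list: `auc`, `mcc`, `f1`, `precision`, `recall`.
#' @export
binary_metrics <- function(y, scores, threshold = 0.5) {
  if (length(y) != length(scores)) stop("y and scores must have the same length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(y == 1 & pred == 1); fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0); tn <- sum(y == 0 & pred == 0)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc,
       mcc = mcc_from_counts(tp, fp, fn, tn),
       f1 = f1,
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' K-category correlation coefficient (RkCC)
#'
#' Gorodkin's R_K statistic computed from a K x K confusion matrix
#' (rows = truth, columns = prediction); the multi-category generalisation
#' of Matthews's correlation coefficient, to which it reduces exactly for
#' K = 2. A degenerate matrix (all mass in a single true class and a single
#' predicted class) returns 0 with attribute `"degenerate"`.
#'
#' @param confusion K x K non-negative count matrix.
#' @return Scalar in `[-1, 1]`.
#' @export
rkcc <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  s <- sum(confusion)
  if (s == 0) stop("confusion matrix must have positive total count")
  corr <- sum(diag(confusion))
  t_k <- rowSums(confusion)  # true-class totals
  p_k <- colSums(confusion)  # predicted-class totals
  num <- corr * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(structure(0, degenerate = TRUE))
  num / den
}

#' Assign functions to shot groups
#'
#' Bins functions by their number of positive training samples: many-shot
#' above the upper threshold, few-shot below the lower threshold, medium-shot
#' in between (inclusive). The full-scale thresholds are 1000 and 200; both
#' are configurable because they only make sense at benchmark scale.
#'
#' @param Y_train Training label matrix (or a named vector of positive
#'   counts).
#' @param thresholds Named vector `c(few = ..., many = ...)`.
#' @return Named factor mapping each function to
#'   `"few"`, `"medium"` or `"many"`.
#' @export
shot_groups <- function(Y_train, thresholds = c(few = 200, many = 1000)) {
  counts <- if (is.matrix(Y_train)) colSums(Y_train) else Y_train
  grp <- ifelse(counts > thresholds[["many"]], "many",
                ifelse(counts < thresholds[["few"]], "few", "medium"))
  factor(grp, levels = c("many", "medium", "few"))
}

#' Macro-F1 per shot group
#'
#' Computes [f1_label()] within each group's function subset; empty groups
#' are reported as `NA` rather than an error.
#'
#' @param Y,Yhat N x C binary matrices.
#' @param groups Factor from [shot_groups()] (length C).
#' @return Named numeric vector with entries `many`, `medium`, `few` and
#'   attribute `"counts"` (functions per group).
#' @export
group_report <- function(Y, Yhat, groups) {
  check_same_shape(Y, Yhat)
  if (length(groups) != ncol(Y)) stop("one group per function required")
  out <- vapply(levels(groups), function(g) {
    cols <- which(groups == g)
    if (length(cols) == 0) return(NA_real_)
    as.numeric(f1_label(Y[, cols, drop = FALSE], Yhat[, cols, drop = FALSE]))
  }, numeric(1))
  structure(out, counts = table(groups))
}

#' Pearson correlation between label columns
#'
#' The C x C matrix of Pearson coefficients between function label vectors
#' over the samples — the label co-occurrence structure the label-embedding
#' module is meant to exploit. Zero-variance columns yield undefined
#' coefficients, reported as 0 and flagged.
#'
#' @param Y N x C binary label matrix (N >= 2).
#' @return C x C symmetric matrix with attribute `"flagged"` (logical matrix
#'   of undefined entries) and `kind = "label_cooccurrence"`.
#' @export
label_cooccurrence_pearson <- function(Y) {
  if (nrow(Y) < 2) stop("need at least 2 samples")
  suppressWarnings(M <- stats::cor(Y))
  flagged <- !is.finite(M)
  M[flagged] <- 0
  structure(M, flagged = flagged, kind = "label_cooccurrence")
}

#' Mean Pearson correlation between function representations
#'
#' For each sample, the Pearson coefficient between every pair of rows of
#' its function representation matrix Z; entry (i, j) is the mean over
#' samples. Correlated functions tend to develop similar representations.
#'
#' @param Z C x d x B array (or list of C x d matrices).
#' @return C x C symmetric matrix with attribute `"flagged"` and
#'   `kind = "representation"`.
#' @export
representation_pearson <- function(Z) {
  if (is.list(Z)) {
    mats <- Z
  } else {
    mats <- lapply(seq_len(dim(Z)[3]), function(b) Z[, , b])
  }
  if (length(mats) == 0) stop("need at least one sample")
  acc <- 0
  flg <- FALSE
  for (M in mats) {
    suppressWarnings(R <- stats::cor(t(M)))
    bad <- !is.finite(R)
    R[bad] <- 0
    acc <- acc + R
    flg <- flg | bad
  }
  structure(acc / length(mats), flagged = flg, kind = "representation")
}

#' Received-attention summaries
#'
#' Averages the last decoder layer's attention weights (all heads) over
#' samples and query positions: per-function received attention is the
#' column mean of the function-function matrices, per-residue-position
#' received attention the column mean of the function-residue matrices.
#' Because every attention row is a probability vector, the per-function
#' received values sum to 1.
#'
#' @param records List of per-sample attention records from
#'   [model_forward()] / [predict_peptides()] with `attention = TRUE`.
#' @return A list: `function_received` (length C), `residue_received`
#'   (length L).
#' @export
attention_summaries <- function(records) {
  if (length(records) == 0) stop("no attention records supplied")
  ff_acc <- 0; fr_acc <- 0; n_ff <- 0; n_fr <- 0
  for (rec in records) {
    ff <- rec$function_function[[length(rec$function_function)]]
    fr <- rec$function_residue[[length(rec$function_residue)]]
    for (t in seq_len(dim(ff)[3])) {
      ff_acc <- ff_acc + colMeans(ff[, , t])
      n_ff <- n_ff + 1
    }
    for (t in seq_len(dim(fr)[3])) {
      fr_acc <- fr_acc + colMeans(fr[, , t])
      n_fr <- n_fr + 1
    }
  }
  list(function_received = ff_acc / n_ff, residue_received = fr_acc / n_fr)
}

#' Full multi-label metrics report
#'
#' Example-based accuracy and macro-F1 from the thresholded calls, plus
#' per-function one-vs-all binary metrics (AUC, MCC, F1, RkCC, precision,
#' recall) and, when shot groups are given, per-group macro-F1.
#'
#' @param Y N x C binary truth matrix.
#' @param probs N x C predicted probability matrix.
#' @param threshold Decision threshold.
#' @param groups Optional factor from [shot_groups()].
#' @return An object of class `mp_metrics_report`: list with `acc_example`,
#'   `f1_label`, `per_function` (data.frame), and `per_group` when groups
#'   were supplied.
#' @export
metrics_report <- function(Y, probs, threshold = 0.5, groups = NULL) {
  check_same_shape(Y, probs)
  Yhat <- (probs > threshold) * 1L
  pf <- lapply(seq_len(ncol(Y)), function(c) {
    bm <- binary_metrics(Y[, c], probs[, c], threshold)
    conf <- table(factor(Y[, c], levels = c(0, 1)),
                  factor(Yhat[, c], levels = c(0, 1)))
    c(bm, list(rkcc = as.numeric(rkcc(unclass(conf)))))
  })
  per_function <- data.frame(
    fn = if (!is.null(colnames(Y))) colnames(Y) else paste0("f", seq_len(ncol(Y))),
    auc = vapply(pf, function(x) x$auc, numeric(1)),
    mcc = vapply(pf, function(x) x$mcc, numeric(1)),
    f1 = vapply(pf, function(x) x$f1, numeric(1)),
    rkcc = vapply(pf, function(x) x$rkcc, numeric(1)),
    precision = vapply(pf, function(x) x$precision, numeric(1)),
    recall = vapply(pf, function(x) x$recall, numeric(1)))
  rep <- list(acc_example = as.numeric(acc_example(Y, Yhat)),
              f1_label = as.numeric(f1_label(Y, Yhat)),
              per_function = per_function,
              threshold = threshold)
  if (!is.null(groups)) rep$per_group <- group_report(Y, Yhat, groups)
  structure(rep, class = "mp_metrics_report")
}

#' @export
print.mp_metrics_report <- function(x, ...) {
  cat(sprintf("Multi-label metrics: ACC_example = %.3f  F1_label = %.3f\n",
              x$acc_example, x$f1_label))
  print(x$per_function, digits = 3, row.names = FALSE)
  if (!is.null(x$per_group)) {
    cat("Per shot group (macro-F1):\n")
    print(round(x$per_group, 3))
  }
  invisible(x)
}

#' Write a metrics report to JSON and TSV
#'
#' @param report An `mp_metrics_report`.
#' @param prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>_per_function.tsv`.
#' @return The JSON path, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  json <- paste0(prefix, ".json")
  out <- list(acc_example = report$acc_example, f1_label = report$f1_label,
              threshold = report$threshold,
              per_function = report$per_function)
  if (!is.null(report$per_group))
    out$per_group <- as.list(report$per_group)
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(report$per_function, paste0(prefix, "_per_function.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(json)
}
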