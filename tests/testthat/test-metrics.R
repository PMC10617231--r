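# Multi-label evaluation metrics against brute-force oracles.

test_that("acc_example equals the set-arithmetic oracle", {
  # worked single-sample example: L = {AMP, TXP}, Lhat = {AMP, ACP}
  vocab <- function_vocabulary()
  Y <- matrix(0L, 1, 15, dimnames = list(NULL, vocab))
  Yh <- Y
  Y[1, c("AMP", "TXP")] <- 1L
  Yh[1, c("AMP", "ACP")] <- 1L
  expect_equal(as.numeric(acc_example(Y, Yh)), 1 / 3)
  # two samples scoring 1 and 1/3 average to 2/3
  Y2 <- rbind(Y, Y); Yh2 <- rbind(Y, Yh)
  expect_equal(as.numeric(acc_example(Y2, Yh2)), 2 / 3)
  expect_equal(as.numeric(acc_example(Y, Y)), 1)
  # random matrices against the oracle
  set.seed(31)
  for (rep in 1:20) {
    A <- matrix(rbinom(100, 1, 0.3), 20, 5)
    B <- matrix(rbinom(100, 1, 0.3), 20, 5)
    expect_equal(as.numeric(acc_example(A, B)), oracle_acc_example(A, B))
  }
  expect_error(acc_example(Y, Y[, 1:3]), "shape")
})

test_that("f1_label equals the per-function oracle and is permutation-symmetric", {
  # function 1 perfect, function 2 all wrong: macro-F1 = 1/2
  Y <- cbind(c(1, 0, 1, 0), c(1, 1, 0, 0))
  Yh <- cbind(Y[, 1], 1 - Y[, 2])
  expect_equal(as.numeric(f1_label(Y, Yh)), 0.5)
  expect_equal(as.numeric(f1_label(Y, Y)), 1)
  set.seed(32)
  for (rep in 1:20) {
    A <- matrix(rbinom(100, 1, 0.4), 20, 5)
    B <- matrix(rbinom(100, 1, 0.4), 20, 5)
    expect_equal(as.numeric(f1_label(A, B)), oracle_f1_label(A, B))
    perm <- sample(5)
    expect_equal(as.numeric(f1_label(A[, perm], B[, perm])),
                 as.numeric(f1_label(A, B)))
  }
})

test_that("binary metrics: AUC by ranks equals pair counting, MCC from counts", {
  # perfectly separating scores
  y <- c(1, 1, 0, 0)
  expect_equal(binary_metrics(y, c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(binary_metrics(y, c(0.9, 0.8, 0.2, 0.1))$mcc, 1)
  # constant scores: AUC 1/2 by the tie convention
  expect_equal(binary_metrics(y, rep(0.7, 4))$auc, 0.5)
  # one discordant pair of four
  expect_equal(binary_metrics(y, c(0.9, 0.4, 0.6, 0.1))$auc, 0.75)
  # degenerate single-class AUC is missing
  expect_true(is.na(binary_metrics(c(1, 1), c(0.2, 0.4))$auc))
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    y <- rbinom(n, 1, 0.5)
    s <- round(runif(n), 1)  # coarse scores force ties
    bm <- binary_metrics(y, s)
    expect_equal(bm$auc, oracle_auc_pairs(y, s))
    tab <- table(factor(y, levels = 0:1), factor(as.integer(s > 0.5), levels = 0:1))
    expect_equal(bm$mcc, oracle_mcc_2x2(tab))
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (rep in 1:20) {
    y <- rbinom(60, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 60) next
    s <- runif(60)
    expect_equal(binary_metrics(y, s)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                                direction = "<", quiet = TRUE))))
  }
})

test_that("rkcc is Gorodkin's statistic and reduces to MCC for K = 2", {
  expect_equal(rkcc(diag(c(5, 3, 2))), 1)
  # uniform confusion: no association
  expect_equal(rkcc(matrix(4, 3, 3)), 0)
  expect_equal(rkcc(matrix(c(5, 1, 2, 7), 2, 2, byrow = TRUE)),
               oracle_mcc_2x2(matrix(c(5, 1, 2, 7), 2, 2, byrow = TRUE)))
  set.seed(34)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(as.numeric(rkcc(tab)), oracle_mcc_2x2(tab), tolerance = 1e-12)
  }
  # degenerate matrix flagged as 0
  deg <- matrix(0, 2, 2); deg[1, 1] <- 10
  expect_equal(as.numeric(rkcc(deg)), 0)
  expect_true(attr(rkcc(deg), "degenerate"))
})

test_that("shot groups bin functions by positive counts", {
  counts <- c(AMP = 1500, TXP = 1000, ABP = 500, AIP = 200, AVP = 199, ACP = 10)
  g <- shot_groups(counts)
  expect_equal(as.character(g[c("AMP", "TXP", "ABP", "AIP", "AVP", "ACP")]),
               c("many", "medium", "medium", "medium", "few", "few"))
  # configurable thresholds for desk-scale data
  g2 <- shot_groups(counts, thresholds = c(few = 100, many = 400))
  expect_equal(as.character(g2[["ABP"]]), "many")
})

test_that("group_report computes macro-F1 within function subsets", {
  Y <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0), c = c(0, 1, 0, 1))
  groups <- factor(c("many", "many", "few"), levels = c("many", "medium", "few"))
  # perfect on the many-shot columns, all-wrong on the few-shot column
  Yh <- cbind(Y[, 1], Y[, 2], 1 - Y[, 3])
  gr <- group_report(Y, Yh, groups)
  expect_equal(unname(gr[c("many", "few")]), c(1, 0))
  expect_true(is.na(gr[["medium"]]))
  # one group holding every function reproduces the global score
  g_all <- factor(rep("many", 3), levels = c("many", "medium", "few"))
  expect_equal(unname(group_report(Y, Yh, g_all)[["many"]]),
               as.numeric(f1_label(Y, Yh)))
  # group sizes recombine to the global macro-F1 as a weighted mean
  cnt <- attr(gr, "counts")
  expect_equal(sum(gr[c("many", "few")] * cnt[c("many", "few")]) / 3,
               as.numeric(f1_label(Y, Yh)))
})

test_that("label co-occurrence Pearson handles the documented cases", {
  Y <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  M <- label_cooccurrence_pearson(Y)
  expect_equal(M["a", "a"], 1)
  expect_equal(M["a", "b"], 0)  # hand-checked independent toy
  Y2 <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  M2 <- label_cooccurrence_pearson(Y2)
  expect_equal(M2["a", "b"], 1)
  expect_equal(M2["a", "c"], -1)
  expect_true(isSymmetric(unclass(M2)[, ]))
  # zero-variance column flagged, reported as 0
  Y3 <- cbind(a = c(1, 0, 1), b = c(1, 1, 1))
  M3 <- label_cooccurrence_pearson(Y3)
  expect_equal(M3["a", "b"], 0)
  expect_true(attr(M3, "flagged")["a", "b"])
})

test_that("representation Pearson averages per-sample row correlations", {
  Z1 <- rbind(c(1, 2, 3), c(1, 2, 3))       # identical rows: +1
  Z2 <- rbind(c(1, 2, 3), c(3, 2, 1))       # reversed rows: -1
  expect_equal(representation_pearson(list(Z1))[1, 2], 1)
  expect_equal(representation_pearson(list(Z2))[1, 2], -1)
  # averaging samples with correlations 1 and 0
  Z3 <- rbind(c(1, 2, 3), c(1, 5, 3))
  r3 <- stats::cor(c(1, 2, 3), c(1, 5, 3))
  expect_equal(representation_pearson(list(Z1, Z3))[1, 2], (1 + r3) / 2)
})

test_that("attention summaries are column means of the last decoder layer", {
  # single record, one head, hand 2x2 function-function matrix
  ff <- array(c(0.9, 0.3, 0.1, 0.7), c(2, 2, 1))
  fr <- array(rep(0.25, 8), c(2, 4, 1))
  rec <- list(function_function = list(ff), function_residue = list(fr))
  s <- attention_summaries(list(rec))
  expect_equal(s$function_received, c(0.6, 0.4))
  expect_equal(sum(s$function_received), 1)
  expect_equal(s$residue_received, rep(0.25, 4))
  # uniform attention gives every function 1/C
  ffu <- array(1 / 2, c(2, 2, 1))
  recu <- list(function_function = list(ffu), function_residue = list(fr))
  expect_equal(attention_summaries(list(recu))$function_received, c(0.5, 0.5))
  expect_error(attention_summaries(list()), "no attention")
})

test_that("metrics_report assembles all pieces consistently", {
  set.seed(35)
  Y <- matrix(rbinom(60, 1, 0.4), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  probs <- matrix(runif(60), 20, 3)
  rep <- metrics_report(Y, probs, groups = shot_groups(Y, c(few = 3, many = 10)))
  expect_s3_class(rep, "mp_metrics_report")
  expect_equal(rep$acc_example, as.numeric(acc_example(Y, (probs > 0.5) * 1L)))
  expect_equal(rep$f1_label, as.numeric(f1_label(Y, (probs > 0.5) * 1L)))
  expect_equal(nrow(rep$per_function), 3)
  expect_equal(rep$per_function$auc[1],
               binary_metrics(Y[, 1], probs[, 1])$auc)
  # serialisation round-trip of the headline numbers
  pre <- withr::local_tempfile()
  write_metrics_report(rep, pre)
  back <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(back$acc_example, rep$acc_example)
})
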