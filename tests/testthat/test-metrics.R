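test_that("confusion counts match a tally-by-loop oracle", {
  set.seed(31)
  truth <- sample(aami_classes(), 100, replace = TRUE)
  pred <- sample(aami_classes(), 100, replace = TRUE)
  cm <- confusion(truth, pred)
  or <- oracle_confusion(truth, pred, aami_classes())
  expect_equal(unname(cm$matrix), unname(or$matrix))
  expect_equal(unname(as.matrix(cm$per_class[, c("TP", "TN", "FP", "FN")])),
               unname(or$per_class))
  # invariants
  expect_true(all(rowSums(cm$per_class[, c("TP", "TN", "FP", "FN")]) == 100))
  expect_equal(unname(rowSums(cm$matrix)),
               unname(as.vector(table(factor(truth, aami_classes())))))
})

test_that("confusion handles the degenerate textbook cases", {
  t1 <- rep("N", 10)
  cm <- confusion(t1, t1)
  expect_equal(sum(cm$matrix) - cm$matrix["N", "N"], 0)
  expect_true(all(cm$per_class[, c("FP", "FN")] == 0))

  cm2 <- confusion(rep("N", 10), rep("V", 10))
  expect_equal(cm2$matrix["N", "V"], 10L)
  expect_equal(sum(cm2$matrix), 10L)
  expect_equal(cm2$per_class["V", "TP"], 0L)
  expect_equal(cm2$per_class["V", "FP"], 10L)

  expect_error(confusion(c("N", "V"), "N"), "length")
  expect_error(confusion("N", "X"), "unknown")
})

test_that("metrics agree with independently coded formulas", {
  set.seed(32)
  for (rep in 1:100) {
    truth <- sample(aami_classes(), 60, replace = TRUE)
    pred <- sample(aami_classes(), 60, replace = TRUE)
    cm <- confusion(truth, pred)
    mr <- metrics(cm)
    for (cls in aami_classes()) {
      cc <- cm$per_class[cls, ]
      om <- oracle_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
      for (nm in c("Acc", "Sen", "Spe", "Ppv", "F1", "MCC")) {
        expect_equal(mr$per_class[cls, nm], om[[nm]], tolerance = 1e-12)
      }
    }
    expect_equal(mr$overall_accuracy, mean(truth == pred), tolerance = 1e-12)
  }
})

test_that("perfect and symmetric-chance classifiers give closed-form metrics", {
  truth <- rep(aami_classes(), each = 10)
  mr <- metrics(confusion(truth, truth))
  expect_true(all(abs(as.matrix(
    mr$per_class[, c("Acc", "Sen", "Spe", "Ppv", "F1", "MCC")]) - 1) < 1e-15))
  expect_equal(mr$overall_accuracy, 1)

  # TP = TN = FP = FN = 25 -> all rates 0.5, MCC = 0
  cm <- structure(list(
    matrix = matrix(c(25L, 25L, 25L, 25L), 2,
                    dimnames = list(true = c("N", "V"), predicted = c("N", "V"))),
    per_class = data.frame(class = c("N", "V"), TP = 25L, TN = 25L,
                           FP = 25L, FN = 25L, row.names = c("N", "V")),
    n = 100L), class = "confusion_counts")
  m2 <- metrics(cm)
  expect_equal(unname(as.matrix(m2$per_class[, c("Acc", "Sen", "Spe", "Ppv")])),
               matrix(0.5, 2, 4))
  expect_equal(m2$per_class$MCC, c(0, 0))
  expect_equal(m2$per_class$F1, c(0.5, 0.5))
})

test_that("the halved F1 convention is available", {
  truth <- c(rep("N", 8), rep("V", 4))
  pred <- c(rep("N", 6), "V", "V", rep("V", 3), "N")
  cm <- confusion(truth, pred)
  std <- metrics(cm, "standard")$per_class$F1
  lit <- metrics(cm, "paper_literal")$per_class$F1
  expect_equal(std, 2 * lit)
})

test_that("zero-denominator cells return 0 with the degenerate flag", {
  truth <- rep("N", 10) # no S present, none predicted
  mr <- metrics(confusion(truth, truth))
  expect_equal(mr$per_class["S", "Sen"], 0)
  expect_equal(mr$per_class["S", "Ppv"], 0)
  expect_true(mr$per_class["S", "degenerate"])
  expect_false(mr$per_class["N", "degenerate"] &&
                 mr$per_class["N", "Ppv"] == 0)
})

test_that("roc_auc matches the Mann-Whitney identity and tie convention", {
  set.seed(33)
  for (rep in 1:10) {
    y <- sample(c("N", "V"), 20, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(runif(20), 1) # coarse scores force ties
    scores <- cbind(N = s, V = 1 - s)
    ra <- roc_auc(scores, y)
    expect_equal(ra$N$auc, oracle_auc_mwu(s, as.integer(y == "N")),
                 tolerance = 1e-12)
  }

  # perfect ranking -> AUC 1; constant scores -> AUC 0.5
  y <- c(rep("V", 5), rep("N", 5))
  sc <- cbind(V = c(0.9, 0.8, 0.95, 0.7, 0.99, 0.1, 0.2, 0.3, 0.05, 0.4))
  expect_equal(roc_auc(sc, y)$V$auc, 1.0)
  const <- cbind(V = rep(0.5, 10))
  expect_equal(roc_auc(const, y)$V$auc, 0.5)
})

test_that("AUC is invariant under monotone score transforms and flags degeneracy", {
  set.seed(34)
  y <- sample(c("N", "V"), 30, replace = TRUE)
  s <- runif(30)
  a1 <- roc_auc(cbind(V = s), y)$V$auc
  a2 <- roc_auc(cbind(V = plogis(5 * s - 2)), y)$V$auc
  expect_equal(a1, a2, tolerance = 1e-12)

  deg <- roc_auc(cbind(V = s), rep("N", 30))
  expect_true(deg$V$degenerate)
  expect_true(is.na(deg$V$auc))
})

test_that("roc_auc agrees with pROC on a random multi-class case", {
  skip_if_not_installed("pROC")
  set.seed(35)
  truth <- sample(aami_classes(), 80, replace = TRUE)
  raw <- matrix(rexp(80 * 5), 80, 5)
  probs <- raw / rowSums(raw)
  colnames(probs) <- aami_classes()
  ra <- roc_auc(probs, truth)
  for (cls in aami_classes()) {
    ref <- as.numeric(pROC::auc(as.integer(truth == cls), probs[, cls],
                                quiet = TRUE, direction = "<"))
    expect_equal(ra[[cls]]$auc, ref, tolerance = 1e-10)
  }
})
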