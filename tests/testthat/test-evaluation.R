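test_that("confusion matrix counts predicted x actual cells", {
  cm <- confusion_matrix(1:4, 1:4)
  expect_equal(unname(diag(cm)), rep(1L, 4))
  expect_equal(sum(cm), 4L)
  cm2 <- confusion_matrix(c(1, 1, 2), c(1, 2, 2))
  expect_equal(cm2[1, 1], 1L)
  expect_equal(cm2[2, 1], 1L)
  expect_equal(cm2[2, 2], 1L)
  expect_equal(sum(cm2), 3L)
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(1, 5), c(1, 1)), "1..4")
})

test_that("class metrics follow the binary TP/TN/FP/FN formulas", {
  # TP=3 TN=5 FP=1 FN=1 for class 1
  y_true <- c(rep(1, 4), rep(2, 6))
  y_pred <- c(1, 1, 1, 2, 1, rep(2, 5))
  m <- class_metrics(confusion_matrix(y_true, y_pred), 1)
  expect_equal(m[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 5L, FP = 1L, FN = 1L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f_score, 0.75)
  # perfect predictions: everything 1
  perfect <- confusion_matrix(rep(1:4, 5), rep(1:4, 5))
  for (cl in 1:4) {
    pm <- class_metrics(perfect, cl)
    expect_equal(unlist(pm[c("accuracy", "sensitivity", "specificity",
                             "precision", "f_score")]),
                 c(accuracy = 1, sensitivity = 1, specificity = 1,
                   precision = 1, f_score = 1))
  }
})

test_that("metrics equal the brute-force counting oracle on random data", {
  set.seed(51)
  for (trial in 1:40) {
    n <- sample(20:80, 1)
    y_true <- sample(1:4, n, replace = TRUE)
    y_pred <- sample(1:4, n, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred)
    for (cl in 1:4) {
      got <- suppressMessages(class_metrics(cm, cl))
      want <- count_metrics_oracle(y_true, y_pred, cl)
      expect_identical(got[c("TP", "TN", "FP", "FN")],
                       want[c("TP", "TN", "FP", "FN")])
      expect_equal(got[5:9], want[5:9])
    }
    expect_equal(total_accuracy(cm), mean(y_true == y_pred))
  }
})

test_that("zero-denominator metrics report 0", {
  cm <- confusion_matrix(rep(2, 5), rep(3, 5))  # class 1 never occurs
  expect_message(m <- class_metrics(cm, 1), "zero denominator")
  expect_equal(m$sensitivity, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$f_score, 0)
  expect_equal(m$specificity, 1)
})

test_that("per-class identities hold on random confusion matrices", {
  set.seed(61)
  for (trial in 1:10) {
    y_true <- sample(1:4, 200, replace = TRUE)
    y_pred <- sample(1:4, 200, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred)
    tps <- vapply(1:4, function(cl) class_metrics(cm, cl)$TP, 0L)
    expect_equal(sum(tps), sum(diag(cm)))
    for (cl in 1:4) {
      m <- class_metrics(cm, cl)
      expect_equal(m$TP + m$TN + m$FP + m$FN, 200L)
      expect_lte(m$f_score, 1)
    }
  }
})

test_that("summaries average identical reports to themselves with zero SD", {
  y_true <- rep(1:4, each = 10)
  y_pred <- c(rep(1, 10), rep(2, 8), 4, 4, rep(3, 10), rep(4, 10))
  r <- eval_report(y_true, y_pred)
  s <- summarize_simulations(list(r, r, r))
  expect_equal(s$total_accuracy[["mean"]], r$total_accuracy)
  expect_equal(s$total_accuracy[["sd"]], 0)
  expect_equal(s$mean_confusion, r$confusion + 0)
  expect_true(all(s$metrics$sd == 0))
  expect_equal(s$n_simulations, 3L)
})

test_that("total accuracy readings: trace/total and mean over classes", {
  cm <- diag(c(500, 200, 100, 39))
  cm[1, 2] <- 161  # trace 839 of total 1000
  expect_equal(total_accuracy(cm), 0.839)
  expect_equal(total_accuracy(diag(4)), 1)
  expect_equal(mean_class_accuracy(diag(c(10, 10, 10, 10))), 1)
})

test_that("ROC sweep matches hand enumeration and the Mann-Whitney oracle", {
  # hand sweep: scores 0.9(+), 0.8(-), 0.3(+) -> AUC 0.5
  rc <- roc_curve(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))
  expect_equal(rc$auc, 0.5)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  # perfectly separated scores
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  # random scores, many trials: exact agreement with Mann-Whitney U
  set.seed(71)
  for (trial in 1:25) {
    n <- sample(30:120, 1)
    scores <- round(runif(n), 2)  # ties on purpose
    pos <- runif(n) < 0.4
    if (sum(pos) == 0 || sum(pos) == n) next
    expect_equal(roc_curve(scores, pos)$auc, auc_mw_oracle(scores, pos),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "ROC undefined")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(81)
  scores <- runif(10000)
  pos <- runif(10000) < 0.5
  expect_gt(roc_curve(scores, pos)$auc, 0.47)
  expect_lt(roc_curve(scores, pos)$auc, 0.53)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(91)
  rc <- roc_curve(rnorm(500), rbinom(500, 1, 0.3) == 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(tail(rc$fpr, 1), tail(rc$tpr, 1)), c(1, 1))
})

test_that("roc_curve agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(101)
  scores <- rnorm(300)
  pos <- rbinom(300, 1, 0.4) == 1
  scores[pos] <- scores[pos] + 1
  ref <- suppressMessages(pROC::auc(pROC::roc(pos, scores, quiet = TRUE)))
  expect_equal(roc_curve(scores, pos)$auc, as.numeric(ref),
               tolerance = 1e-12)
})

test_that("mean ROC reproduces identical curves and stays monotone", {
  set.seed(111)
  scores <- rnorm(200); pos <- rbinom(200, 1, 0.5) == 1
  rc <- roc_curve(scores, pos)
  avg <- mean_roc(list(rc, rc, rc))
  single <- mean_roc(list(rc))
  expect_equal(avg$tpr, single$tpr, tolerance = 1e-12)
  expect_true(all(diff(avg$tpr) >= 0))
  # averaging distinct curves lands between them pointwise
  rc2 <- roc_curve(scores + ifelse(pos, 2, 0), pos)
  both <- mean_roc(list(rc, rc2))
  lo <- pmin(mean_roc(list(rc))$tpr, mean_roc(list(rc2))$tpr)
  hi <- pmax(mean_roc(list(rc))$tpr, mean_roc(list(rc2))$tpr)
  expect_true(all(both$tpr >= lo - 1e-12 & both$tpr <= hi + 1e-12))
})

test_that("normality test behaves on normal, bimodal and degenerate input", {
  set.seed(121)
  p_normal <- vapply(1:100, function(s) {
    set.seed(s)
    normality_test(rnorm(50))$p_value
  }, 0)
  expect_gte(mean(p_normal > 0.05), 0.9)
  bimodal <- c(rep(0, 25), rep(1, 25)) + rnorm(50, sd = 1e-3)
  expect_lt(normality_test(bimodal)$p_value, 0.01)
  expect_error(normality_test(c(1, 2)), "3 <= n")
  expect_error(normality_test(rep(1, 10)), "constant")
})
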