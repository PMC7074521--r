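test_that("confusion matrices count labels with rows = truth", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
               dimnames = list(true = c("A", "B"),
                               predicted = c("A", "B"))),
               ignore_attr = "class")
  expect_equal(sum(cm), 3)
  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(perfect == diag(1, 3)))
  expect_error(confusion_matrix("A", "Z", classes = c("A", "B")))
  expect_error(confusion_matrix(c("A", "B"), "A"))
})

test_that("the published ensemble matrix reproduces every printed rate", {
  cm <- published_confusion("mv", "test")
  expect_equal(ccr(cm), 99.10, tolerance = 0.005)
  expect_equal(misclassified(cm), 1592)
  metrics <- class_metrics(cm)
  expect_equal(metrics$error, c(1.38, 0.879, 0.443), tolerance = 0.005)
  expect_equal(metrics$f1[metrics$class == "Azad"], 99.77,
               tolerance = 0.005)
})

test_that("the single-classifier matrices reproduce their printed CCRs", {
  expect_equal(ccr(published_confusion("pso", "test")), 98.65,
               tolerance = 0.005)
  expect_equal(ccr(published_confusion("aco", "test")), 98.94,
               tolerance = 0.005)
  expect_equal(ccr(published_confusion("hs", "test")), 98.99,
               tolerance = 0.005)
  expect_equal(misclassified(published_confusion("pso", "test")), 2385)
})

test_that("identity matrices score perfectly and empty ones error", {
  ident <- confusion_matrix(rep(c("A", "B", "C"), 10),
                            rep(c("A", "B", "C"), 10))
  expect_equal(ccr(ident), 100)
  m <- class_metrics(ident)
  expect_true(all(m$recall == 100 & m$precision == 100 & m$f1 == 100))
  expect_error(ccr(matrix(0, 3, 3)))
})

test_that("the one-vs-rest CCR route equals the trace route", {
  set.seed(6)
  for (k in 1:30) {
    cm <- matrix(sample(0:50, 9, TRUE), 3, 3)
    if (sum(cm) == 0) next
    # per-class accuracy route: (TP + TN) / total, averaged via totals
    tp <- sum(diag(cm))
    expect_equal(ccr(cm), 100 * tp / sum(cm))
    met <- class_metrics(cm)
    # F1 symmetric in precision/recall
    with_swap <- 2 * met$recall * met$precision /
      (met$recall + met$precision)
    with_swap[is.nan(with_swap)] <- 0
    expect_equal(met$f1, with_swap)
  }
})

test_that("the alternative diagonal TN bookkeeping is available", {
  cm <- published_confusion("mv", "test")
  std <- class_metrics(cm, tn = "standard")
  alt <- class_metrics(cm, tn = "diagonal")
  expect_false(isTRUE(all.equal(std$specificity, alt$specificity)))
  expect_equal(std$recall, alt$recall)  # TN does not enter recall
})

test_that("ROC endpoints and symmetry behave", {
  truth <- rep(c(TRUE, FALSE), each = 20)
  sep <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  expect_equal(roc_auc(sep, truth), 1)
  expect_equal(roc_auc(-sep, truth), 0)
  set.seed(13)
  s <- rnorm(400); t <- s + rnorm(400) > 0
  expect_equal(roc_auc(-s, t), 1 - roc_auc(s, t), tolerance = 1e-12)
  rc <- roc_curve(s, t)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(all(rc$fpr >= 0 & rc$fpr <= 1 & rc$tpr >= 0 & rc$tpr <= 1))
  expect_error(roc_curve(s, rep(TRUE, 400)))
})

test_that("our AUC agrees with an independent implementation", {
  set.seed(29)
  s <- rnorm(300)
  t <- (s + rnorm(300)) > 0.2
  ours <- roc_auc(s, t)
  ref <- as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("precision-recall area behaves at its known baselines", {
  truth <- rep(c(TRUE, FALSE), each = 15)
  sep <- c(runif(15, 0.8, 1), runif(15, 0, 0.2))
  expect_equal(pr_auc(sep, truth), 1)
  expect_equal(pr_auc(rnorm(10), rep(TRUE, 10)), 1)
  set.seed(31)
  t <- runif(20000) < 0.3
  expect_equal(pr_auc(runif(20000), t), 0.3, tolerance = 0.02)
  expect_error(pr_auc(rnorm(5), rep(FALSE, 5)))
})

test_that("iteration summaries compute mean, sd and box statistics", {
  s <- summarize_iterations(c(98, 100))
  expect_equal(s$mean, 99)
  expect_equal(s$sd, sqrt(2))
  expect_equal(summarize_iterations(1:5)$median, 3)
  cons <- summarize_iterations(rep(7, 4))
  expect_equal(cons$sd, 0)
  expect_error(summarize_iterations(1))
})

test_that("confusion CSV io round-trips", {
  cm <- published_confusion("hs", "val")
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  expect_equal(unclass(read_confusion_csv(path)), unclass(cm))
})
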